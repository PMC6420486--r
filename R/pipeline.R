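#' Configuration for a full pipeline run
#'
#' One seed drives every stage: each stage derives its own seed via
#' \code{\link{stage_seed}} so that stages are independently
#' reproducible.
#'
#' @param seed master seed.
#' @param out_dir output directory; \code{NULL} keeps results in memory
#'   only.
#' @param generator named list of \code{\link{generator_config}}
#'   overrides.
#' @param impute run the censored-count imputation stage (default TRUE;
#'   with no censored cells the stage is a no-op).
#' @param imputation named list of \code{\link{imputation_spec}}
#'   overrides.
#' @param sensitivities run the three sensitivity fits (default TRUE).
#' @param pca_var_frac variance fraction for the PCA sensitivity.
#' @param margins data.frame (\code{state_id}, \code{victory_margin}) for
#'   the counterfactual stage; default uses the first three generated
#'   states with the three closest published swing-state margins (0.22,
#'   0.72, 0.76 points).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, generator = list(),
                       impute = TRUE, imputation = list(),
                       sensitivities = TRUE, pca_var_frac = 0.9,
                       margins = NULL) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 generator = generator, impute = impute,
                 imputation = imputation, sensitivities = sensitivities,
                 pca_var_frac = pca_var_frac, margins = margins),
            class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> votes -> rates -> impute -> compare -> fit ->
#' counterfactual, each stage seeded from the master seed. Emits (when
#' \code{out_dir} is set) the county panel, net-gain table,
#' Table-1/2-shaped comparison CSVs, the Table-3-shaped model summary,
#' the counterfactual CSV, imputation diagnostics, a YAML config echo and
#' a run log. Re-running with the same config reproduces every output.
#'
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{pipeline_result} with elements
#'   \code{sim}, \code{classification}, \code{rates}, \code{imputation},
#'   \code{comparisons}, \code{design}, \code{fit},
#'   \code{sensitivities}, \code{counterfactual}, \code{log}.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- c(
    paste("countyswing", as.character(utils::packageVersion("countyswing"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("seed", config$seed))
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. simulate
  gen_cfg <- do.call(generator_config,
                     c(list(seed = stage_seed(config$seed, 1)),
                       config$generator))
  sim <- stage("simulate", generate_panel(gen_cfg))
  note("simulate: ", nrow(sim$panel), " counties, ",
       sum(sim$deaths$suppressed), " suppressed cells")

  ## 2. votes
  cls <- stage("votes", classify_counties(sim$panel))
  note("votes: ", paste(names(cls$counts), cls$counts,
                        sep = "=", collapse = " "))

  ## 3. rates (all-cause and other streams are fully observed)
  observed <- sim$deaths[sim$deaths$cause_group != "despair", ]
  rates <- stage("rates", age_adjust(observed))

  ## 4. impute
  n_cens <- sum(sim$deaths$suppressed)
  imp <- NULL
  despair_note <- NULL
  if (n_cens == 0) {
    despair_note <- "no imputation needed"
    imp_tables <- list(sim$deaths[sim$deaths$cause_group == "despair", ])
  } else if (!config$impute) {
    despair_note <- "imputation disabled; despair comparisons skipped"
    imp_tables <- NULL
  } else {
    imp_spec <- do.call(imputation_spec,
                        c(list(seed = stage_seed(config$seed, 4)),
                          config$imputation))
    imp <- stage("impute",
                 fit_imputation_model(sim$deaths,
                                      censoring_rule(gen_cfg$suppression_threshold),
                                      imp_spec))
    imp_tables <- imp$datasets
    note("impute: M=", imp$M, ", max Rhat ",
         round(max(imp$diagnostics$rhat), 4))
  }
  if (!is.null(despair_note)) note("impute: ", despair_note)

  ## 5. compare (gain groups; both_gain counties enter both groups)
  lab <- cls$labels
  in_r <- lab$county_id[lab$label %in% c("republican_gain", "both_gain")]
  in_d <- lab$county_id[lab$label %in% c("democratic_gain", "both_gain")]
  if (length(in_d) < 2 || length(in_r) < 2) {
    # small panels can lack one gain category entirely; fall back to
    # comparing gain-classified counties against the both-decline group
    note("compare: democratic-gain group too small; ",
         "comparing republican-gain vs both-decline counties")
    in_d <- lab$county_id[lab$label == "both_decline"]
  }
  if (length(in_d) < 2 || length(in_r) < 2)
    abort_input("cannot form two county groups of >= 2 for comparisons; ",
                "panel too small")
  cmp_ids <- c(in_r, in_d)
  cmp_grp <- factor(rep(c("republican_gain", "democratic_gain"),
                        c(length(in_r), length(in_d))),
                    levels = c("democratic_gain", "republican_gain"))
  pan <- sim$panel
  rowi <- match(cmp_ids, pan$county_id)
  cmp_states <- pan$state_id[rowi]

  comparison_vars <- c(
    stats::setNames(paste0(names(gen_cfg$covariate_change_means), "_2015"),
                    paste0(names(gen_cfg$covariate_change_means), "_2015")))
  comparisons <- stage("compare", {
    res <- lapply(names(comparison_vars), function(v) {
      r <- compare_groups(pan[[comparison_vars[v]]][rowi], cmp_grp, cmp_states)
      data.frame(variable = v,
                 mean_republican = r$means[["republican_gain"]],
                 sd_republican = r$sds[["republican_gain"]],
                 mean_democratic = r$means[["democratic_gain"]],
                 sd_democratic = r$sds[["democratic_gain"]],
                 difference = r$difference, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    })
    # all-cause adjusted rates, both periods and the change
    rc <- rate_change(rates[rates$cause_group == "all_cause", ])
    for (v in c("rate_2000", "rate_2015", "delta")) {
      x <- rc[[v]][match(cmp_ids, rc$county_id)]
      r <- compare_groups(x, cmp_grp, cmp_states)
      res[[length(res) + 1]] <- data.frame(
        variable = paste0("all_cause_", v),
        mean_republican = r$means[["republican_gain"]],
        sd_republican = r$sds[["republican_gain"]],
        mean_democratic = r$means[["democratic_gain"]],
        sd_democratic = r$sds[["democratic_gain"]],
        difference = r$difference, p_value = r$p_value,
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, res)
    # despair rates: per imputed dataset, Rubin-combined
    if (!is.null(imp_tables)) {
      per_diff <- vapply(imp_tables, function(tt) {
        rcd <- rate_change(age_adjust(tt))
        x <- rcd$delta[match(cmp_ids, rcd$county_id)]
        r <- compare_groups(x, cmp_grp, cmp_states)
        c(r$difference, (r$difference / r$statistic)^2,
          r$means[["republican_gain"]], r$means[["democratic_gain"]])
      }, numeric(4))
      if (ncol(per_diff) >= 2) {
        cb <- rubin_combine(per_diff[1, ], per_diff[2, ])
        pval <- rubin_p_value(cb)
      } else {
        cb <- list(estimate = per_diff[1, 1],
                   total_variance = per_diff[2, 1])
        z <- cb$estimate / sqrt(cb$total_variance)
        pval <- 2 * stats::pnorm(-abs(z))
      }
      tab <- rbind(tab, data.frame(
        variable = "despair_delta",
        mean_republican = mean(per_diff[3, ]),
        sd_republican = NA_real_,
        mean_democratic = mean(per_diff[4, ]),
        sd_democratic = NA_real_,
        difference = cb$estimate, p_value = pval,
        stringsAsFactors = FALSE))
    }
    tab
  })

  ## 6. fit
  design <- stage("fit", build_design(sim$panel, rates))
  fit <- stage("fit", fit_primary(design))
  sens <- if (config$sensitivities)
    stage("fit", sensitivity_suite(design, config$pca_var_frac)) else NULL
  note("fit: n=", fit$n, ", R2 fixed ", round(fit$r2["fixed"], 3),
       ", total ", round(fit$r2["total"], 3))

  ## 7. counterfactual
  margins <- config$margins
  if (is.null(margins))
    margins <- data.frame(
      state_id = fit$state_slopes$state_id[1:3],
      victory_margin = c(0.22, 0.72, 0.76))
  cf <- stage("counterfactual", electoral_counterfactual(fit, margins))

  result <- list(sim = sim, classification = cls, rates = rates,
                 imputation = imp, comparisons = comparisons,
                 design = design, fit = fit, sensitivities = sens,
                 counterfactual = cf, log = log_lines)
  class(result) <- "pipeline_result"

  if (!is.null(config$out_dir)) write_pipeline(result, config)
  result
}

# internal: emit the CSV/JSON bundle for a pipeline run
write_pipeline <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sim(result$sim, dir)
  utils::write.csv(result$classification$labels,
                   file.path(dir, "net_gain.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$rates),
                   file.path(dir, "rates.csv"), row.names = FALSE)
  utils::write.csv(result$comparisons,
                   file.path(dir, "table1_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(result$fit$coefficients,
                   file.path(dir, "table3_fixed_effects.csv"),
                   row.names = FALSE)
  fit_json <- list(
    coefficients = result$fit$coefficients,
    random = result$fit$random,
    r2 = as.list(result$fit$r2),
    r2_convention = result$fit$r2_convention,
    pop_slopes = as.list(result$fit$pop_slopes),
    state_slopes = result$fit$state_slopes,
    n = result$fit$n)
  jsonlite::write_json(fit_json, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(result$counterfactual),
                   file.path(dir, "counterfactual.csv"), row.names = FALSE)
  if (!is.null(result$imputation))
    jsonlite::write_json(result$imputation$diagnostics,
                         file.path(dir, "imputation_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:\n")
  cat(paste(" ", x$log), sep = "\n")
  invisible(x)
}
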