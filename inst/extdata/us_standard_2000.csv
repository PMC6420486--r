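age_group,weight
<1,0.013818
1-4,0.055317
5-14,0.145565
15-24,0.138646
25-34,0.135573
35-44,0.162613
45-54,0.134834
55-64,0.087247
65-74,0.066037
75-84,0.044842
85+,0.015508
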