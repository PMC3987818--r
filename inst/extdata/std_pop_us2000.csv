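age_group,weight
18-24,0.129793436552814
25-34,0.190752582481816
35-44,0.215889343877442
45-54,0.180166859838545
55-64,0.116075671784203
65+,0.16732210546518
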