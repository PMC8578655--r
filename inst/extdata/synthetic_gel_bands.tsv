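sample_id	genotype	band_170	band_196	band_274
S0001	TT	99.4	558.8	405.7
S0002	TT	110.9	516.4	419.2
S0003	TT	93.4	488.1	407.9
S0004	TC	180.2	458.9	331.9
S0005	TC	183.2	452.7	316.4
S0006	TC	240.7	430.2	384.5
S0007	CC	253.1	389.7	304
S0008	CC	313.5	420.5	274.4
S0009	CC	257.1	409.4	264.3
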