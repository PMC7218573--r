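sample_id	ko_keep_high	ko_keep_edge	ko_drop_groupB	ko_filler
s1	10	6	100	999884
s2	10	4	100	999886
s3	10	6	2	999982
s4	10	4	3	999983
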