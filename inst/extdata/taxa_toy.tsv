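sample_id	sp_keep_dom	sp_keep_edge	sp_drop_groupB	sp_keep_filler
s1	0.4	0.002	0.5	0.098
s2	0.4	0.0005	0.5	0.0995
s3	0.4	0.002	0.0005	0.5975
s4	0.4	0.002	0.0008	0.5972
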