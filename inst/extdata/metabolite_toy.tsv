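sample_id	m_keep_flat	m_drop_rsd	m_drop_sim	m_drop_unid	m_drop_absent	m_keep_ok
s1	10	1	10	10	5	8
s2	10	3	11	10		9
s3	10		10	11		10
s4	10		11	11		11
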