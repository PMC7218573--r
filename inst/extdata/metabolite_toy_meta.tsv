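feature_id	similarity	identified
m_keep_flat	500	TRUE
m_drop_rsd	600	TRUE
m_drop_sim	150	TRUE
m_drop_unid	500	FALSE
m_drop_absent	500	TRUE
m_keep_ok	300	TRUE
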