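marker	chr	bp	allele_b6	allele_d2
rs_synth_01	1	173220000	A	G
rs_synth_02	1	173424810	A	G
rs46128598	1	173450010	A	G
rs_synth_03	1	173583966	A	G
rs_synth_04	1	173765510	A	G
rs_synth_05	1	173927399	A	G
rs_synth_06	1	174149625	A	G
rs_synth_07	1	174355267	A	G
rs_synth_08	1	174513014	A	G
rs_synth_09	1	174771391	A	G
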