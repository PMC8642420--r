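snp_id
rs12916
rs10066707
rs17238484
rs2006760
rs2303152
rs5909
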