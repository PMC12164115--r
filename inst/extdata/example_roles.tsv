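gene	role	cancer_type
driver01	oncogene	NA
driver02	tsg	NA
driver02	oncogene	SIM
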