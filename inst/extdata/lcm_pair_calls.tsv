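patient_id	tumor_call	stroma_call
P01	BL1	MSL
P02	BL1	MSL
P03	BL1	MSL
P04	BL1	MSL
P05	BL2	BL2
P06	M	BL2
P07	M	M
P08	MSL	MSL
P09	M	MSL
P10	LAR	LAR
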