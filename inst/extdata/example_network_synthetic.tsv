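regulator_id	target_gene	sign	molecule_type
REG_A	G1	activation	kinase
REG_A	G2	activation	kinase
REG_A	G3	inhibition	kinase
REG_A	G4	activation	kinase
REG_A	G5	activation	kinase
REG_B	G3	inhibition	miRNA
REG_B	G4	inhibition	miRNA
REG_B	G5	activation	miRNA
REG_B	G6	inhibition	miRNA
REG_C	G1	activation	transcription regulator
REG_C	G4	inhibition	transcription regulator
REG_C	G6	activation	transcription regulator
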