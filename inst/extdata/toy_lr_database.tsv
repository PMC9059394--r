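id	ligand_name	ligand_subunits	receptor_name	receptor_subunits	pathway	agonists	antagonists	co_stimulatory	co_inhibitory	category
PW01_I1	LG001	LG001	RCA001	RCA001	PW01	AG02				ecm_receptor
PW01_I2	LG002	LG002	RCA002_RCB002	RCA002_RCB002	PW01					cell_contact
PW02_I1	LG003	LG003	RCA003	RCA003	PW02	AG04				secreted
PW02_I2	LG004	LG004	RCA004_RCB004	RCA004_RCB004	PW02		AN02			ecm_receptor
PW03_I1	LG005	LG005	RCA005	RCA005	PW03	AG01				cell_contact
PW03_I2	LG006	LG006	RCA006_RCB006	RCA006_RCB006	PW03					secreted
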