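# Core tetraether lipid registry: branched GDGT / OB-GDGT / brGMGT species
# detected in euxinic water columns, with molecular formulas, series
# derivation from the base species brGDGT-1a, and the nominal [M+H]+ m/z
# used for reporting. `steps` is a comma-separated list of series steps
# applied to `parent`. `note` records chromatographic metadata only.
name	series_class	formula	parent	steps	nominal_mz	note
brGDGT-1a	brGDGT	C66H132O6			1022	base species of the branched series
brGDGT-2a	brGDGT	C67H134O6	brGDGT-1a	methylation	1036	
brGDGT-2b	brGDGT	C67H132O6	brGDGT-1a	methylation,ring	1034	
brGDGT-3a	brGDGT	C68H136O6	brGDGT-1a	methylation,methylation	1050	dominant in euxinic waters
brGMGT-1a	brGMGT	C66H130O6	brGDGT-1a	gmgt_bridge	1020	reverse-phase elution as a double peak 0.4 and 0.7 min after brGDGT-1a
OB-GDGT-9	OB-GDGT	C71H142O6	brGDGT-1a	methylation,methylation,methylation,methylation,methylation	1092	
OB-GDGT-10	OB-GDGT	C72H144O6	brGDGT-1a	methylation,methylation,methylation,methylation,methylation,methylation	1106	
OB-GDGT-11	OB-GDGT	C73H146O6	brGDGT-1a	methylation,methylation,methylation,methylation,methylation,methylation,methylation	1120	
OB-GDGT-12	OB-GDGT	C74H148O6	brGDGT-1a	methylation,methylation,methylation,methylation,methylation,methylation,methylation,methylation	1134	
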