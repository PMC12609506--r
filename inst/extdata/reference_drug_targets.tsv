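drug	target	approved	known_action
Fostamatinib	CAMK1	TRUE	TRUE
Fostamatinib	JAK2	TRUE	TRUE
Fostamatinib	MAPK14	TRUE	TRUE
Fostamatinib	PRKCD	TRUE	TRUE
Fostamatinib	PTK2	TRUE	TRUE
Minocycline	CASP3	TRUE	TRUE
Minocycline	MAPK1	TRUE	TRUE
Minocycline	MAPK14	TRUE	TRUE
Minocycline	MAPK3	TRUE	TRUE
Acetylsalicylic acid	CASP3	TRUE	TRUE
Acetylsalicylic acid	MAPK1	TRUE	TRUE
Acetylsalicylic acid	MAPK3	TRUE	TRUE
Arsenic trioxide	MAPK3	TRUE	TRUE
Arsenic trioxide	MAPK1	TRUE	TRUE
Arsenic trioxide	AKT1	TRUE	TRUE
Copper	APP	TRUE	TRUE
Copper	GAPDH	TRUE	TRUE
Copper	HSP90AA1	TRUE	TRUE
Benzoyl peroxide	PRKCA	TRUE	TRUE
Benzoyl peroxide	PRKCD	TRUE	TRUE
Dequalinium	PRKCA	FALSE	TRUE
Dequalinium	PRKCD	FALSE	TRUE
Ingenol mebutate	PRKCD	TRUE	TRUE
Ingenol mebutate	PRKCA	TRUE	TRUE
Tamoxifen	PRKCA	TRUE	TRUE
Tamoxifen	PRKCD	TRUE	TRUE
Abrocitinib	JAK2	TRUE	TRUE
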