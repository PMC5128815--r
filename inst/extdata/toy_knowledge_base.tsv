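gene	alteration_class	therapy	indication	phase	requires_her2_positive
PIK3CA	snv	PI3K pathway inhibitor	breast	early	FALSE
PIK3CA	snv	PI3K alpha inhibitor	breast	early	FALSE
PIK3CA	snv	AKT inhibitor	breast	early	FALSE
PIK3CA	snv	everolimus + trastuzumab + chemotherapy	breast	late	TRUE
ERBB2	amplification	trastuzumab	breast	approved	FALSE
ERBB2	snv	neratinib	breast	early	FALSE
ERBB2	indel	neratinib	breast	early	FALSE
FGF3	amplification	dovitinib	breast	early	FALSE
FGF4	amplification	dovitinib	breast	early	FALSE
TOP2A	amplification	anthracycline (neoadjuvant)	breast	late	TRUE
BRCA1	snv	olaparib	other	late	FALSE
BRCA2	snv	olaparib	other	late	FALSE
PTEN	deep_deletion	AKT inhibitor	other	early	FALSE
CDK4	amplification	palbociclib	other	approved	FALSE
CCND1	amplification	CDK4/6 inhibitor	breast	early	FALSE
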