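name	family	accession	species	sequence	known_cys_count	synonyms
destabilase I	destabilase	AAA96144	Hirudo medicinalis		14	destabilase;lysozyme;destabilase i
LDTI	ldti	AAB33769	Hirudo medicinalis		6	leech-derived tryptase inhibitor;ldti;tryptase inhibitor;kazal
hirudin	hirudin	APA20833	Hirudo verbana		8	hirudin;hirudin-3;hirudin variant;thrombin inhibitor
bdellin	bdellin	P09865	Hirudo medicinalis		6	bdellin;bdellin b-3;kazal
eglin C	eglin	0905140A	Hirudo medicinalis		0	eglin;eglin c;potato inhibit
ghilanten	antistasin-family	AAB21233	Haementeria ghilianii		25	ghilanten;antistasin
guamerin	antistasin-family	AAD09442	Hirudo nipponia		9	guamerin;antistasin
piguamerin	antistasin-family	P81499	Hirudo nipponia		10	piguamerin;guamerin;antistasin
antistasin	antistasin-family	P15358	Haementeria officinalis		21	antistasin;ghilanten
bdellastasin	antistasin-family	1C9P	Hirudo medicinalis		10	bdellastasin;antistasin
cystatin	cystatin	AAN28679	Theromyzon tessulatum		1	cystatin;cystatin b
manillase	manillase	patent-2006-US-7.049.124-B1	Hirudinaria manillensis		0	manillase;hyaluronoglucoronidase;hyaluronoglucuronidase;glyco hydro
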