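name	forward	reverse	description
universal_V4	CCAGCASCYGCGGTAATTCC	ACTTTCGTTCTTGATYRA	Eukaryotic 18S V4 "universal" pair TAReuk454FWD1 / TAReukREV3, ~380-450 bp products
nonmetazoan_V4	CYGCGGTAATTCCAGCTC	AYGGTATCTRATCRTCTTYG	Alternative eukaryotic V4 pair E572F / E1009R used in non-metazoan workflows
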