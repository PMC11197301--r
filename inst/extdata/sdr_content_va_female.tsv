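# Gene content of the Vitis amurensis (Amur grape) female-haplotype putative
# sex-determination region, chr2:5,055,465-5,198,824 (16 genes, in genomic
# order). The aldolase-TPP fusion gene carries both functional labels (two
# rows, one gene id).
gene_id	label
Vitis02G0494	PPR-containing protein
Vitis02G0495	YABBY transcription factor
Vitis02G0496	SKU5
Vitis02G0497	beta-fructofuranosidase
Vitis02G0498	aldolase
Vitis02G0498	trehalose-6-phosphate phosphatase
Vitis02G0499	inaperturate pollen1
Vitis02G0500	uncharacterized protein
Vitis02G0501	exostosin family protein
Vitis02G0502	KASIII
Vitis02G0503	PLATZ transcription factor
Vitis02G0504	flavin-containing monooxygenase
Vitis02G0505	flavin-containing monooxygenase
Vitis02G0506	flavin-containing monooxygenase
Vitis02G0507	FSEX
Vitis02G0508	WRKY transcription factor
Vitis02G0509	APT3
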