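# Gene content of the Vitis vinifera 'Cabernet Sauvignon' female-haplotype
# sex-determination region (17 genes, in genomic order). Per-gene ids for
# this haplotype are not packaged; placeholder ids are used and only the
# functional labels are compared.
gene_id	label
VvF_01	PPR-containing protein
VvF_02	YABBY transcription factor
VvF_03	SKU5
VvF_04	beta-fructofuranosidase
VvF_05	aldolase
VvF_06	trehalose-6-phosphate phosphatase
VvF_07	inaperturate pollen1
VvF_08	exostosin family protein
VvF_09	KASIII
VvF_10	PLATZ transcription factor
VvF_11	flavin-containing monooxygenase
VvF_12	flavin-containing monooxygenase
VvF_13	flavin-containing monooxygenase
VvF_14	flavin-containing monooxygenase
VvF_15	FSEX
VvF_16	WRKY transcription factor
VvF_17	APT3
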