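##gff-version 3
##sequence-region chr2 1 30000000
# Synthetic stand-in annotation: the 16 genes of the Vitis amurensis putative
# sex-determination region (chr2:5,055,465-5,198,824). Gene ids are real;
# per-gene coordinates are not public, so genes are placed evenly across the
# interval (4-kb models every 8,960 bp).
chr2	synthetic	gene	5055465	5059464	.	+	.	ID=Vitis02G0494
chr2	synthetic	gene	5064425	5068424	.	+	.	ID=Vitis02G0495
chr2	synthetic	gene	5073385	5077384	.	+	.	ID=Vitis02G0496
chr2	synthetic	gene	5082345	5086344	.	+	.	ID=Vitis02G0497
chr2	synthetic	gene	5091305	5095304	.	+	.	ID=Vitis02G0498
chr2	synthetic	gene	5100265	5104264	.	+	.	ID=Vitis02G0499
chr2	synthetic	gene	5109225	5113224	.	+	.	ID=Vitis02G0500
chr2	synthetic	gene	5118185	5122184	.	+	.	ID=Vitis02G0501
chr2	synthetic	gene	5127145	5131144	.	+	.	ID=Vitis02G0502
chr2	synthetic	gene	5136105	5140104	.	+	.	ID=Vitis02G0503
chr2	synthetic	gene	5145065	5149064	.	+	.	ID=Vitis02G0504
chr2	synthetic	gene	5154025	5158024	.	+	.	ID=Vitis02G0505
chr2	synthetic	gene	5162985	5166984	.	+	.	ID=Vitis02G0506
chr2	synthetic	gene	5171945	5175944	.	+	.	ID=Vitis02G0507
chr2	synthetic	gene	5180905	5184904	.	+	.	ID=Vitis02G0508
chr2	synthetic	gene	5194825	5198824	.	+	.	ID=Vitis02G0509
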