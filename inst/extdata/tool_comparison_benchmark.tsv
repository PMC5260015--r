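# Benchmark of 16 experimentally characterised 9 bp DNA targets (5'->3') with their
# literature-reported optimal ZFP helices (F1+F2+F3 flattened to 21 residues) and the
# predictions of three tools; '-' = no prediction returned. Identity columns hold the
# published Hamming identities (truncated to 2 decimals).
target	experimental	zifnn	zifnn_identity	zifit	zifit_identity	zftools	zftools_identity
GTGGAGGAA	QSGNLTRRSGHLTRRSGELTR	DSGHLTRDSGHLTRDSGHLTR	0.76	RNVNLVTRQDNLGRQASNLLR	0.33	RSDELVRRSDNLVRQSSNLVR	0.47
GCTGCTGCT	RSGELTRTSGELTRRSGELTR	TSGELTETSGELTETSGELTE	0.76	LRASLRRQRSDLTRMKNTLTR	0.38	TSGELVRTSGELVRTSGELVR	0.76
GAGGAGGAT	QSGNLTRRSGNLTRRSGNLTR	QSGHLTRQSGHLTRQSGHLTR	0.76	-	-	RSDNLVRRSDNLVRTSGNLVR	0.66
CTGGCGGCA	RSGALTERSGDLTRQSGDLTR	RSGDLTTRSGDLTTRSGDLTT	0.76	-	-	RNDALTERSDDLVRQSGDLRR	0.76
GGGGCGGGG	KSGHLTARSGELTRRSGHLTK	RSGHLTRRSGHLTRRSGHLTR	0.80	RKHRLDGRTDTLARRGNHLRR	0.33	RSDKLVRRSDDLVRRSDKLVR	0.42
GCTGGGGGC	RSGELTRTSGHLTRDSGHLTR	QSGHLTRQSGHLTRQSGHLTR	0.80	VSNSLARRREHLVRTNSKLTR	0.42	TSGELVRRSDKLVRDPGHLVR	0.61
GCGTGGGGA	RSGELTRRSGHLTRQSGHLTR	QSGTLTRRSGTLTRQSGTLTR	0.80	-	-	RSDDLVRRSDHLTTQRAHLER	0.61
GCGTGGGCA	RSGELTRRSGHLTRRSGELTR	RSGTLTRRSGTLTRRSGTLTT	0.80	-	-	RSDDLVRRSDDLVRQSGDLRR	0.57
GCGTGGGAA	RSGELTRRSGHLTRQSGNLTR	RSGTLTRRSGTLTRRSGTLTR	0.80	-	-	RSDDLVRRSDHLTTQSSNLVR	0.66
GCGGGCCGC	RSGELTRDSGALTRRSGELTR	RSGHLTRRSGHLTRRSGHLTR	0.80	-	-	RSDDLVRDPGHLVRHTGHLLE	0.47
GCAGCGGAC	RSGELTRRSGHLTRQSGSLTR	QSGHLTRQSGHLTRQSGHLTR	0.80	QKGTLGRRTDTLARDPSNLIR	0.38	QSGDLRRRSDDLVRDPGNLVR	0.52
GAGGAAGGG	RSGHLTRQSGNLTRRSGNLTR	QSGHLTRQSGHLTRQSGHLTR	0.80	RRDNLNRQQTNLTRKRERLDR	0.48	RSDNLVRQSSNLVRRSDKLVR	0.61
ACTACTGGA	TSGDLTRTSGDLTRQSGHLTR	TSGELTRTSGELTRTSGELTR	0.80	-	-	THLDLIRTHLDLIRQRAHLER	0.57
GCTGGGGGC	QSGDLTRRSGHLTRDSGHLTR	QSGHLTRQSGHLTRQSGHLTR	0.85	VSNSLARRREHLVRTNSKLTR	0.48	TSGELVRRSDKLVRDPGHLVR	0.61
GAAGAGGGT	QSGHLTRRSGNLTRQSGNLTR	QSGHLTRQSGHLTRQSGHLTR	0.85	QRNNLGRRQDNLGRTRQKLET	0.38	QSSNLVRRSDNLVRTSGHLVR	0.61
GAGGAAGGT	TSGHLTRTSGHLTRRSGELTR	TSGHLTRTSGHLTRTSGHLTR	0.90	RRDNLNRQQTNLTRTKQRLEV	0.28	RSDNLVRQSSNLVRTSGHLVR	0.47
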