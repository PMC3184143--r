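gene_id	pcr_result	FindPeaks	MACS	PeakSeq	USeq
LOC_Os01g04800	+	+	-	+	+
LOC_Os01g18440	+	+	-	+	+
LOC_Os01g18584	+	+	-	+	+
LOC_Os02g07430	+	+	-	+	+
LOC_Os02g45850	+	+	-	+	+
LOC_Os03g63810	+	+	-	+	-
LOC_Os04g41229	+	-	-	+	-
LOC_Os05g11130	+	+	-	+	+
LOC_Os05g20930	+	-	-	+	-
LOC_Os05g48990	+	-	-	+	-
LOC_Os06g11330	+	+	-	+	+
LOC_Os07g13260	+	+	-	+	+
LOC_Os08g02160	+	-	-	+	-
LOC_Os08g06370	+	+	-	+	+
LOC_Os09g24490	+	+	-	+	+
LOC_Os10g39130	+	-	-	+	-
LOC_Os11g29870	+	+	+	+	+
LOC_Os12g10540	+	+	+	+	+
LOC_Os03g09930	-	-	-	-	-
LOC_Os01g10504	-	-	-	-	-
LOC_Os12g43640	-	-	-	-	-
LOC_Os12g44380	-	-	-	-	-
LOC_Os07g40570	-	-	-	+	-
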