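# Literature-derived signed interactions around interferon-gamma priming
# of macrophage STAT1 activity (STAT1p = phosphorylated STAT1).
# source <TAB> sign <TAB> target <TAB> provenance
TNF	+	STAT1p	direct
S100A9	+	P38	direct
P38	+	STAT1p	indirect
S100A9	+	IL6	direct
IL6	+	STAT1p	indirect
IL15	+	STAT1p	direct
IL2RG	+	STAT1p	direct
SOCS1	-	STAT1p	direct
IFNG	+	STAT1p	direct
IFNG	+	SOCS1	indirect
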