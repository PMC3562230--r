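name	sequence	strand	reaction
U-fwd	TGTTTAGATGATGATTTGTTTA	+	U
U-rev	ATCAATCATACACTAAATCAAT	-	U
M-fwd	CGTTTAGACGATGATTCGTTTA	+	M
M-rev	ATCGATCATACGCTAAATCGAT	-	M
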