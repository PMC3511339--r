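# motif library: consensus rows (family<TAB>matrix<TAB>IUPAC<TAB>core=a-b)
# AP-1 TPA-response element, near-palindromic, matches both strands;
# NFkB decamer. Cores follow the upper-case rendering convention.
V$AP-1F	V$AP-1.01	TGASTCA	core=3-6
V$NFKB	V$NFKAPPAB.01	GGGRNNYYCC	core=1-4
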