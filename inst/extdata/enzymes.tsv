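name	site
AfaI	GTAC
AluI	AGCT
ApaI	GGGCCC
BamHI	GGATCC
BglII	AGATCT
DraI	TTTAAA
EcoRI	GAATTC
EcoRV	GATATC
HaeIII	GGCC
HhaI	GCGC
HindIII	AAGCTT
KpnI	GGTACC
MboI	GATC
MspI	CCGG
PstI	CTGCAG
SacI	GAGCTC
SalI	GTCGAC
XbaI	TCTAGA
XhoI	CTCGAG
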