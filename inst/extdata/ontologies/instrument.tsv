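term	id	synonyms
Q Exactive	MS:1001911	QExactive|Thermo Q Exactive
Orbitrap Fusion Lumos	MS:1002732	Fusion Lumos
LTQ Orbitrap XL	MS:1000556
6550 iFunnel Q-TOF LC/MS	MS:1002783	Agilent 6550 Q-TOF
timsTOF Pro	MS:1003005	Bruker timsTOF Pro
TSQ Quantum Ultra	MS:1000751
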