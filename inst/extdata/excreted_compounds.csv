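compound,concentration_um,method
Ala,264,LC-MS
Glu,15.0,LC-MS
Ile,327,LC-MS
Lys,23.4,NMR
Phe,36.0,LC-MS
Tyr,39.6,LC-MS
Val,239,LC-MS
Hse,93.3,NMR
Hse-lactone,222,NMR
Unknown 3,119,NMR
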