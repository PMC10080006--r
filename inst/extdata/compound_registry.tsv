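name	formula
Ala	C3H7NO2
Arg	C6H14N4O2
Asn	C4H8N2O3
Asp	C4H7NO4
Cys	C3H7NO2S
Glu	C5H9NO4
Gln	C5H10N2O3
Gly	C2H5NO2
His	C6H9N3O2
Ile	C6H13NO2
Leu	C6H13NO2
Lys	C6H14N2O2
Met	C5H11NO2S
Phe	C9H11NO2
Pro	C5H9NO2
Ser	C3H7NO3
Thr	C4H9NO3
Trp	C11H12N2O2
Tyr	C9H11NO3
Val	C5H11NO2
Hse	C4H9NO3
Hse-lactone	C4H7NO2
Unknown 3	C4H9NO2
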