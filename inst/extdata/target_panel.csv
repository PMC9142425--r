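analyte,class,formula,lod,loq,blank,was,was_label,ps,ps_label,recovery
PFBA,PFCA,C4HF7O2,7.7,25.7,0,,nd,,nd,0.14
PFPeA,PFCA,C5HF9O2,1.2,4.1,0,,lt_loq,,nd,0.85
PFHxA,PFCA,C6HF11O2,0.6,2.1,0,6.5,q,,lt_loq,0.92
PFHpA,PFCA,C7HF13O2,0.5,1.5,3.3,,nr,,nr,0.95
PFOA,PFCA,C8HF15O2,0.5,1.7,0.5,7.5,q,4.2,q,1.02
PFNA,PFCA,C9HF17O2,1.0,3.5,0,,lt_loq,,lt_loq,0.98
PFDA,PFCA,C10HF19O2,0.9,2.9,0,8.0,q,3.6,q,0.96
PFUdA,PFCA,C11HF21O2,1.6,5.2,0,21.1,q,8.7,q,0.88
PFDoA,PFCA,C12HF23O2,1.4,4.6,0,8.9,q,,nd,0.81
PFTrDA,PFCA,C13HF25O2,0.8,2.8,0,84.6,q,,nd,0.78
PFTeDA,PFCA,C14HF27O2,0.8,2.8,0,,nd,,nd,0.72
PFPrS,PFSA,C3HF7O3S,0.6,1.9,0,,nd,,nd,0.90
PFBS,PFSA,C4HF9O3S,0.6,1.9,0,,nd,,nd,0.93
PFPeS,PFSA,C5HF11O3S,0.6,2.0,0,,nd,,nd,0.95
PFHxS,PFSA,C6HF13O3S,0.6,2.0,0,,lt_loq,,nd,0.99
PFHpS,PFSA,C7HF15O3S,0.9,3.0,1.0,,nd,,nd,0.97
PFOS,PFSA,C8HF17O3S,1.0,3.3,3.0,30.6,q,15.3,q,1.05
PFNS,PFSA,C9HF19O3S,1.0,3.3,0,,nd,,nd,0.91
PFDS,PFSA,C10HF21O3S,1.0,3.3,0,,lt_loq,,nd,0.87
4:2 FTS,FTS,C6H5F9O3S,0.8,2.8,0,,nd,,nd,1.10
6:2 FTS,FTS,C8H5F13O3S,0.8,2.6,0,,nd,,nd,1.15
8:2 FTS,FTS,C10H5F17O3S,1.2,4.2,92.7,,nr,,nr,1.20
FBSA,FASA,C4H2F9NO2S,4.7,15.5,0,,nd,,nd,0.75
FOSA,FASA,C8H2F17NO2S,4.7,15.5,0,,lt_loq,,nd,0.70
N-EtFOSAA,FASAA,C12H8F17NO4S,3.8,12.6,0,,lt_loq,,nd,0.45
N-MeFOSAA,FASAA,C11H6F17NO4S,2.8,9.3,0,48.3,q,33.8,q,0.50
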