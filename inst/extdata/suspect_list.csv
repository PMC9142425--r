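id,name,cas,formula,smiles,class
PFBA,Perfluorobutanoic acid,375-22-4,C4HF7O2,OC(=O)C(F)(F)C(F)(F)C(F)(F)F,PFCA
PFPeA,Perfluoropentanoic acid,2706-90-3,C5HF9O2,,PFCA
PFHxA,Perfluorohexanoic acid,307-24-4,C6HF11O2,,PFCA
PFHpA,Perfluoroheptanoic acid,375-85-9,C7HF13O2,,PFCA
PFOA,Perfluorooctanoic acid,335-67-1,C8HF15O2,OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,PFCA
PFNA,Perfluorononanoic acid,375-95-1,C9HF17O2,,PFCA
PFDA,Perfluorodecanoic acid,335-76-2,C10HF19O2,,PFCA
PFUdA,Perfluoroundecanoic acid,2058-94-8,C11HF21O2,,PFCA
PFDoA,Perfluorododecanoic acid,307-55-1,C12HF23O2,,PFCA
PFTrDA,Perfluorotridecanoic acid,72629-94-8,C13HF25O2,,PFCA
PFTeDA,Perfluorotetradecanoic acid,376-06-7,C14HF27O2,,PFCA
PFPrS,Perfluoropropanesulfonic acid,423-41-6,C3HF7O3S,,PFSA
PFBS,Perfluorobutanesulfonic acid,375-73-5,C4HF9O3S,,PFSA
PFPeS,Perfluoropentanesulfonic acid,2706-91-4,C5HF11O3S,,PFSA
PFHxS,Perfluorohexanesulfonic acid,355-46-4,C6HF13O3S,,PFSA
PFHpS,Perfluoroheptanesulfonic acid,375-92-8,C7HF15O3S,,PFSA
PFOS,Perfluorooctanesulfonic acid,1763-23-1,C8HF17O3S,,PFSA
PFNS,Perfluorononanesulfonic acid,68259-12-1,C9HF19O3S,,PFSA
PFDS,Perfluorodecanesulfonic acid,335-77-3,C10HF21O3S,,PFSA
4:2 FTS,4:2 Fluorotelomer sulfonic acid,757124-72-4,C6H5F9O3S,,FTS
6:2 FTS,6:2 Fluorotelomer sulfonic acid,27619-97-2,C8H5F13O3S,,FTS
8:2 FTS,8:2 Fluorotelomer sulfonic acid,39108-34-4,C10H5F17O3S,,FTS
FBSA,Perfluorobutanesulfonamide,30334-69-1,C4H2F9NO2S,,FASA
FOSA,Perfluorooctanesulfonamide,754-91-6,C8H2F17NO2S,,FASA
N-EtFOSAA,N-Ethyl perfluorooctanesulfonamidoacetic acid,2991-50-6,C12H8F17NO4S,,FASAA
N-MeFOSAA,N-Methyl perfluorooctanesulfonamidoacetic acid,2355-31-9,C11H6F17NO4S,,FASAA
53FTCA,"5:3 Fluorotelomer carboxylic acid (2H,2H,3H,3H-perfluorooctanoic acid)",914637-49-3,C8H5F11O2,OC(=O)CCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,FTCA
62diPAP,6:2/6:2 Fluorotelomer diphosphate ester,57677-95-9,C16H9F26O4P,,diPAP
MPFPA,"4,4,5,5,5-Pentafluoro-2-methylpentanoic acid",,C6H7F5O2,CC(C(O)=O)CC(F)(F)C(F)(F)F,other
BSPFPH,"N'-(Benzenesulfonyl)-2,2,3,3,3-pentafluoropropanimidohydrazide",,C9H8F5N3O2S,,other
PFBGEE,N-(Perfluorobutanoyl)glutamic acid 1-ethyl ester,,C11H12F7NO5,,other
NFHSUA,"11-[(3,3,4,4,5,5,6,6,6-Nonafluorohexyl)sulfanyl]undecanoic acid",,C17H25F9O2S,,other
122PFPA,"1H,1H,2H,2H-Perfluorotetradecaphosphonic acid",,C14H6F25O3P,,phosphonic
82FTOH,8:2 Fluorotelomer alcohol,678-39-7,C10H5F17O,,FTOH
HFPO-DA,Hexafluoropropylene oxide dimer acid (GenX),13252-13-6,C6HF11O3,,ether
PFEESA,Perfluoro(2-ethoxyethane)sulfonic acid,113507-82-7,C4HF9O4S,,ether
ADONA,"4,8-Dioxa-3H-perfluorononanoic acid",919005-14-4,C7H2F12O4,,ether
PFECHS,Perfluoroethylcyclohexanesulfonic acid,335-24-0,C8HF15O3S,,ether
NaPFOA,Perfluorooctanoate sodium salt,335-95-5,C8F15O2Na,,other
POLYFL1,Polyfluorinated polymer segment (synthetic decoy),,C30H4F58O4,,other
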