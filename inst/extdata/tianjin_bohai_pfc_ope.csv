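name,group,cas,formula,half_life_days,medium,mec_ng_per_l,pnec_ng_per_l,c_printed
PFOS,Perfluorinated compounds,1763-23-1,C8HF17O3S,1.48 × 10^4^,water,1.61,1000,0.0041
PFOA,Perfluorinated compounds,335-67-1,C8HO2F15,1.58 × 10^3^,water,15.1,"100,000",0.038
TEP,Organophosphate esters,78-40-0,C6H15O4P,4.90,water,1.683,9.0 × 10^5^,12.24
TEHP,Organophosphate esters,78-42-2,C24H51O4P,4.23,water,47.4,5.0 × 10^5^,14.18
TCEP,Organophosphate esters,115-96-8,C6H12Cl3O4P,3.68,water,473.79,5.1 × 10^4^,16.30
TCPP,Organophosphate esters,13674-84-5,C9H18Cl3O4P,3.68,water,6.3,4.5 × 10^4^,16.30
TDCP,Organophosphate esters,13674-87-8,C12H15Cl6O4P,4.08,water,3.249,3.9 × 10^4^,14.71
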