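ingredient,class,route,dose_mg_per_kg,hpcia
amoxicillin,penicillins,injectable,10,FALSE
amoxicillin,penicillins,oral_other,20,FALSE
benzylpenicillin,penicillins,injectable,10,FALSE
sulfadimidine,sulfonamides,oral_premix,25,FALSE
trimethoprim,diaminopyrimidines,oral_premix,5,FALSE
chlortetracycline,tetracyclines,oral_premix,40,FALSE
oxytetracycline,tetracyclines,injectable,10,FALSE
tylosin,macrolides,injectable,10,TRUE
tulathromycin,macrolides,injectable,2.5,TRUE
colistin,polypeptides,oral_other,5,TRUE
enrofloxacin,fluoroquinolones,injectable,2.5,TRUE
ceftiofur,cephalosporins,injectable,3,TRUE
gentamicin,aminoglycosides,injectable,4,FALSE
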