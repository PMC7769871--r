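product_id,ingredient,concentration_mg_per_unit,unit,route
pen_inj_150,amoxicillin,150,ml,injectable
pen_oral_500,amoxicillin,500,g,oral_other
sulfa_premix_100,sulfadimidine,100,g,oral_premix
tetra_premix_100,chlortetracycline,100,g,oral_premix
oxytet_inj_200,oxytetracycline,200,ml,injectable
tylosin_inj_200,tylosin,200,ml,injectable
colistin_oral_50,colistin,50,g,oral_other
enro_inj_100,enrofloxacin,100,ml,injectable
ceftiofur_inj_50,ceftiofur,50,ml,injectable
genta_inj_50,gentamicin,50,ml,injectable
tmps_premix,sulfadimidine,100,g,oral_premix
tmps_premix,trimethoprim,20,g,oral_premix
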