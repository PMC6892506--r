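name,K_r,K_r_star,K_LMC,K_MC
Pfizer,1,3,2,3
GSK,2,1,8,15
Bayer,3,8,14,10
J&J,4,10,1,1
Novartis,5,2,3,4
Merck,6,4,6,6
Lilly,7,6,16,14
Roche,8,11,4,2
AstraZeneca,9,5,19,16
Sanofi,10,12,10,9
BMS,11,9,15,11
Abbott,12,7,13,12
Illumina,13,29,24,24
Amgen,14,14,11,8
Novo Nordisk,15,21,9,7
Allergan,16,33,12,20
Celgene,17,20,17,17
Biogen,18,16,18,18
Mylan,19,25,28,28
Gilead,20,13,7,13
Shire,21,17,21,21
Takeda,22,22,23,23
Astellas,23,28,29,27
Daiichi Sankyo,24,18,32,29
AbbVie,25,15,5,5
Regeneron,26,32,22,22
Eisai,27,24,33,31
Stryker,28,31,20,19
BioMarin,29,19,34,33
Zoetis,30,26,27,26
Vertex,31,23,25,25
Alexion,32,30,26,30
Perrigo,33,34,31,34
Incyte,34,27,30,32
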