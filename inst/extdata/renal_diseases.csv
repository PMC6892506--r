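name,short_name,K_r,K_r_star,category
Alport syndrome,Alport,1,6,glomerular
Bardet-Biedl syndrome,Bardet-Biedl,2,1,ciliopathies
Fabry disease,Fabry,3,7,tubular_metabolic
Kallmann syndrome,KS,4,2,congenital
Renal tubular acidosis,RTA,5,4,tubular_metabolic
Cystinuria,Cystinuria,6,5,nephrolithiasis
Renal agenesis,Renal agenesis,7,14,congenital
Nephronophthisis,Nephronophthisis,8,16,ciliopathies
X-linked hypophosphatemia,XLH,9,33,tubular_metabolic
Bartter syndrome,Bartter,10,8,tubular_metabolic
Xanthinuria,Xanthinuria,11,41,nephrolithiasis
Oculocerebrorenal syndrome,Oculocerebrorenal,12,3,tubular_metabolic
Nail-patella syndrome,Nail-patella,13,17,glomerular
Familial renal amyloidosis,Amyloidosis,14,45,glomerular
Episodic ataxia,EA,15,9,tubular_metabolic
Gitelman syndrome,Gitelman,16,24,tubular_metabolic
Medullary cystic kidney disease,MCKD,17,21,tubular_metabolic
Familial hypocalciuric hypercalcemia,FHH,18,32,tubular_metabolic
Renal glycosuria,Glycosuria,19,42,tubular_metabolic
Fanconi-Bickel syndrome,Fanconi-Bickel,20,40,tubular_metabolic
Liddle's syndrome,Liddle,21,23,tubular_metabolic
Hypomagnesemia with secondary hypocalcemia,HSH,22,31,tubular_metabolic
Fraser syndrome,Fraser,23,13,congenital
WAGR syndrome,WAGR,24,36,congenital
Branchio-oto-renal syndrome,BOR,25,19,congenital
Townes-Brocks syndrome,Townes-Brocks,26,26,congenital
Autosomal dominant hypophosphatemic rickets,ADHR,27,44,tubular_metabolic
Orofaciodigital syndrome 1,Orofaciodigital,28,18,ciliopathies
Denys-Drash syndrome,DDS,29,28,glomerular
Perlman syndrome,Perlman,30,10,congenital
Simpson-Golabi-Behmel syndrome,SGBS,31,11,congenital
Caroli disease,Caroli,32,12,ciliopathies
Congenital nephrotic syndrome,GNS,33,25,glomerular
Fechtner syndrome,Fechtner,34,39,glomerular
Abderhalden-Kaufmann-Lignac syndrome,AKL,35,27,tubular_metabolic
Lysinuric protein intolerance,LPI,36,22,tubular_metabolic
Majewski's polydactyly syndrome,Majewski,37,47,ciliopathies
Urofacial syndrome,Urofacial,38,20,congenital
Barakat syndrome,Barakat,39,15,congenital
Dicarboxylic aminoaciduria,DCBXA,40,35,tubular_metabolic
MODY 5,MODY 5,41,38,congenital
Papillorenal syndrome,Papillorenal,42,30,congenital
OCRL,OCRL,43,43,tubular_metabolic
COQ9,COQ9,44,37,tubular_metabolic
Juvenile nephronophthisis,J. nephronophthisis,45,29,ciliopathies
Renal-hepatic-pancreatic dysplasia,RHPD,46,46,ciliopathies
Conorenal syndrome,Conorenal,47,34,ciliopathies
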