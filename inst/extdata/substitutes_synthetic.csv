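food_id,name,dairy_subtype,energy,carbohydrate,protein,fat,fiber,dha,calcium,iron,zinc,iodine,potassium,vitamin_a,vitamin_b1,vitamin_b2,vitamin_b3,vitamin_b6,vitamin_b9,vitamin_b12,vitamin_c,vitamin_d
soymilk,Soymilk (synthetic placeholder; per 100 g product - verify against label),NONE,31,1.2,3.0,1.6,1.1,0,10,0.4,0.3,0,117,0,0.02,0.02,0.2,0.04,28,0,0,0
cow_milk,Cow's milk (synthetic placeholder; per 100 g product - verify against label),LIQUID_MILK,62,4.8,3.0,3.4,0,0,104,0.3,0.42,1.9,109,24,0.03,0.14,0.1,0.04,5,0.4,1,0
fmp_psc,FMP-PSC reconstituted (synthetic placeholder; per 100 g liquid equivalent - verify against label),LIQUID_MILK,79,7.6,2.2,3.5,1.2,9,120,1.25,1.1,15,80,60,0.05,0.10,0.5,0.05,15,0.4,8,1.2
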