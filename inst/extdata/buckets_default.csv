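# Default 27-bucket integration table, 1.03-8.52 ppm.
# anchored = TRUE marks buckets whose bounds follow named resonances;
# filler buckets tile the remaining unexcluded span and are unanchored.
low_ppm,high_ppm,label,anchored
1.03,1.14,methylsuccinate,FALSE
1.14,1.25,hydroxybutyrate_3,TRUE
1.25,1.34,lactate,TRUE
1.34,1.44,filler_1.34,FALSE
1.44,1.52,alanine,TRUE
1.52,1.61,filler_1.52,FALSE
1.87,1.99,acetate,TRUE
1.99,2.13,n_acetyl,TRUE
2.14,2.29,acetone,TRUE
2.29,2.41,filler_2.29,FALSE
2.53,2.70,citrate,TRUE
2.98,3.14,creatinine,TRUE
3.14,3.99,glucose_bulk,TRUE
4.00,4.20,filler_4.00,FALSE
4.21,4.40,filler_4.21,FALSE
5.17,5.36,glucose_c1h,TRUE
5.57,5.85,urea,FALSE
6.84,6.96,filler_6.84,FALSE
6.97,7.08,filler_6.97,FALSE
7.15,7.33,indoxyl_sulphate,TRUE
7.34,7.44,filler_7.34,FALSE
7.45,7.54,filler_7.45,FALSE
7.55,7.71,hippurate,TRUE
7.72,7.86,filler_7.72,FALSE
7.87,8.01,filler_7.87,FALSE
8.15,8.33,filler_8.15,FALSE
8.34,8.52,formate,FALSE
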