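id,walk,weight_kg,breed,sex,gps_dist_m,algo_dist_m
D1.1,1,NA,Mixed,MN,2590,3307
D1.1,2,NA,Mixed,MN,2430,3355
D1.2,1,NA,Mixed,MN,732,953
D1.2,2,NA,Mixed,MN,878,957
D1.2,3,NA,Mixed,MN,699,974
D1.3,1,NA,Mixed,FN,577,712
D1.4,1,NA,Mixed,MN,815,847
D1.4,2,NA,Mixed,MN,568,579
D1.5,1,20,Labrador,FN,852,609
D1.5,2,20,Labrador,FN,1310,812
D1.6,1,13,Toy Poodle,MN,921,1446
D1.7,1,17,Springer Spaniel,FN,1830,2853
D1.8,1,34,Rottweiler,FN,776,851
D1.9,1,15,Collie,MN,1330,1240
D1.10,1,17,Collie Cross,MN,650,688
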