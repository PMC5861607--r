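id,height_cm,weight_kg,breed,age,sex,steps_video,steps_algorithm
D.1,47.4,17.5,Springer Spaniel,9,FN,455,398
D.2,51.5,27,Mixed,8,FN,351,309
D.3,54,28.1,Labrador,5,FN,348,307
D.4,50.5,28.2,Mixed,10,FN,313,274
D.5,53.4,18.1,Lurcher,6,MN,311,269
D.6,60.6,39,Labrador,2,MI,275,242
D.7,45.8,11.3,Lurcher,1.9,F,323,293
D.8,64.4,25,Lurcher,9,MN,331,305
D.9,46.8,12,Springer Spaniel/Collie,5,FN,414,370
D.10,84.9,64.0,Irish Wolf hound,5.5,FN,274,274
D.11,38,11.8,Corgi,3.5,FN,491,455
D.12,44.4,15,Cocker Spaniel/Poodle,2,MN,489,374
D.13,61.5,38,Rhodesian Ridgeback,7,FN,320,281
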