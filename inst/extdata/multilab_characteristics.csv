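study_id,species,sex,n,centers_experimental,centers_nonexperimental,dual_role_centers
MC01,dog,both,51,3,1,0
MC02,mouse,both,384,3,0,0
MC03,swine,F,60,3,0,0
MC04,swine,NR,32,2,0,0
MC05,mouse,M,47,3,3,0
MC05,rabbit,M,23,3,3,0
MC05,swine,F,26,3,3,0
MC06,mouse,M,315,5,1,0
MC07,mouse,M,241,5,1,1
MC08,rat,M,140,3,1,0
MC09,rat,M,130,3,1,0
MC10,rat,M,135,3,1,0
MC11,mouse,F,NR,4,0,0
MC12,rat,M,128,3,1,0
MC13,rat,M,142,3,1,0
MC14,rat,M,72,3,0,0
MC15,rat,M,111,3,1,0
MC16,mouse,M,108,3,0,0
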