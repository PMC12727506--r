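group_id,taxon_class,species_level
amp01,amphibian,FALSE
amp02,amphibian,FALSE
amp03,amphibian,FALSE
amp04,amphibian,FALSE
amp05,amphibian,FALSE
amp06,amphibian,FALSE
amp07,amphibian,FALSE
amp08,amphibian,FALSE
amp09,amphibian,FALSE
amp10,amphibian,FALSE
rep01,reptile,FALSE
rep02,reptile,FALSE
rep03,reptile,FALSE
rep04,reptile,FALSE
rep05,reptile,FALSE
rep06,reptile,FALSE
rep07,reptile,FALSE
rep08,reptile,FALSE
rep09,reptile,FALSE
rep10,reptile,FALSE
brd01,bird,FALSE
brd02,bird,FALSE
brd03,bird,FALSE
brd04,bird,FALSE
brd05,bird,FALSE
brd06,bird,FALSE
brd07,bird,FALSE
brd08,bird,FALSE
brd09,bird,FALSE
brd10,bird,FALSE
brd11,bird,FALSE
brd12,bird,FALSE
brd13,bird,FALSE
brd14,bird,FALSE
brd15,bird,FALSE
brd16,bird,FALSE
brd17,bird,FALSE
brd18,bird,FALSE
brd19,bird,FALSE
brd20,bird,FALSE
mam01,mammal,FALSE
mam02,mammal,FALSE
mam03,mammal,FALSE
mam04,mammal,FALSE
mam05,mammal,FALSE
mam06,mammal,FALSE
mam07,mammal,FALSE
mam08,mammal,FALSE
mam09,mammal,FALSE
mam10,mammal,FALSE
mam11,mammal,FALSE
mam12,mammal,FALSE
mam13,mammal,FALSE
mam14,mammal,FALSE
mam15,mammal,FALSE
mam16,mammal,FALSE
mam17,mammal,FALSE
mam18,mammal,FALSE
mam19,mammal,FALSE
mam20,mammal,FALSE
mam21,mammal,FALSE
mam22,mammal,FALSE
mam23,mammal,FALSE
mam24,mammal,FALSE
lmm01,mammal,TRUE
lmm02,mammal,TRUE
lmm03,mammal,TRUE
lmm04,mammal,TRUE
lmm05,mammal,TRUE
lmm06,mammal,TRUE
lmm07,mammal,TRUE
lmm08,mammal,TRUE
lmm09,mammal,TRUE
lmm10,mammal,TRUE
lmm11,mammal,TRUE
lmm12,mammal,TRUE
frb01,forb,FALSE
frb02,forb,FALSE
frb03,forb,FALSE
frb04,forb,FALSE
frb05,forb,FALSE
frb06,forb,FALSE
frb07,forb,FALSE
frb08,forb,FALSE
frb09,forb,FALSE
frb10,forb,FALSE
frb11,forb,FALSE
frb12,forb,FALSE
frb13,forb,FALSE
frb14,forb,FALSE
frb15,forb,FALSE
frb16,forb,FALSE
frb17,forb,FALSE
frb18,forb,FALSE
frb19,forb,FALSE
frb20,forb,FALSE
frb21,forb,FALSE
frb22,forb,FALSE
frb23,forb,FALSE
frb24,forb,FALSE
frb25,forb,FALSE
trs01,tree_shrub,FALSE
trs02,tree_shrub,FALSE
trs03,tree_shrub,FALSE
trs04,tree_shrub,FALSE
trs05,tree_shrub,FALSE
trs06,tree_shrub,FALSE
trs07,tree_shrub,FALSE
trs08,tree_shrub,FALSE
trs09,tree_shrub,FALSE
trs10,tree_shrub,FALSE
trs11,tree_shrub,FALSE
trs12,tree_shrub,FALSE
trs13,tree_shrub,FALSE
trs14,tree_shrub,FALSE
trs15,tree_shrub,FALSE
trs16,tree_shrub,FALSE
trs17,tree_shrub,FALSE
trs18,tree_shrub,FALSE
trs19,tree_shrub,FALSE
trs20,tree_shrub,FALSE
trs21,tree_shrub,FALSE
trs22,tree_shrub,FALSE
trs23,tree_shrub,FALSE
trs24,tree_shrub,FALSE
trs25,tree_shrub,FALSE
trs26,tree_shrub,FALSE
trs27,tree_shrub,FALSE
trs28,tree_shrub,FALSE
trs29,tree_shrub,FALSE
trs30,tree_shrub,FALSE
grm01,graminoid,FALSE
grm02,graminoid,FALSE
grm03,graminoid,FALSE
grm04,graminoid,FALSE
grm05,graminoid,FALSE
grm06,graminoid,FALSE
grm07,graminoid,FALSE
grm08,graminoid,FALSE
grm09,graminoid,FALSE
grm10,graminoid,FALSE
grm11,graminoid,FALSE
grm12,graminoid,FALSE
grm13,graminoid,FALSE
grm14,graminoid,FALSE
grm15,graminoid,FALSE
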