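rsid,chrom,pos,risk_allele,other_allele,allelic_or,risk_allele_freq
rs9285413,15,853704,C,A,1.13079599420205,0.200373776443303
rs9236106,7,2395541,G,T,1.22522160282582,0.212438167817891
rs9757414,18,3685666,C,A,1.40377650841473,0.851348970830441
rs9459385,3,5494635,G,T,1.34914309507585,0.449184668250382
rs9160996,22,8021033,T,G,1.20318281275408,0.852177066914737
rs9917117,13,10990987,C,T,1.26132104876196,0.80831211488694
rs9805346,11,11906162,C,A,1.34391744442469,0.657513224333525
rs9792579,8,13238495,G,A,1.28845301462353,0.798022198304534
rs9558691,20,14823597,A,G,1.17472253543878,0.650676983781159
rs9606511,18,15427504,T,C,1.44863558923393,0.350870593637228
rs9597875,7,19758475,C,A,1.34937539053761,0.630448942445219
rs9956521,20,24784101,T,C,1.12641859678724,0.7473812751472
rs9710894,18,25310819,A,G,1.37617101781256,0.81772690359503
rs9176920,11,26787100,T,C,1.43988379093376,0.68038164395839
rs9277230,16,26955109,G,A,1.40520660337503,0.860472934506834
rs9536565,16,28027538,C,A,1.20764605879161,0.543600414507091
rs9280196,13,30985427,T,G,1.34715034693403,0.856786267086864
rs9132009,14,35546966,C,T,1.12094864719167,0.635389412380755
rs9590711,2,39569558,T,G,1.05559519503069,0.121768597327173
rs9807895,17,39824856,A,C,1.07384251621352,0.826003341190517
rs9664016,15,44431364,T,C,1.07585234531455,0.824567637033761
rs9626080,18,45919510,G,T,1.21193529962885,0.446161370165646
rs9408215,8,45990306,T,G,1.11638465659613,0.361903438158333
rs9580304,12,46354012,G,A,1.37253702741698,0.341919543407857
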