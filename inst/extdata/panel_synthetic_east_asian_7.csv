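rsid,chrom,pos,risk_allele,other_allele,allelic_or,risk_allele_freq
rs9285413,15,853704,C,A,1.13079599420205,0.200373776443303
rs9236106,7,2395541,G,T,1.22522160282582,0.212438167817891
rs9757414,18,3685666,C,A,1.40377650841473,0.851348970830441
rs9459385,3,5494635,G,T,1.34914309507585,0.449184668250382
rs9160996,22,8021033,T,G,1.20318281275408,0.852177066914737
rs9917117,13,10990987,C,T,1.26132104876196,0.80831211488694
rs9805346,11,11906162,C,A,1.34391744442469,0.657513224333525
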