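year,age_class,n_at_risk,n_harvested
1996,juvenile,23,0
1996,adult,32,7
1997,juvenile,12,2
1997,adult,46,13
1998,juvenile,4,2
1998,adult,16,8
1999,juvenile,30,3
1999,adult,9,5
2000,juvenile,8,2
2000,adult,33,17
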