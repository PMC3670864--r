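year,spring_npr_juvenile,spring_npr_adult,fall_harvest_juvenile,fall_harvest_adult,poult_hen_ratio,archer_index
1995,,,,,1.4,
1996,53,279,253,208,2.1,364
1997,60,174,114,94,1.8,188
1998,102,255,414,115,3.1,541
1999,185,197,149,154,2.1,263
2000,101,406,340,133,2.8,365
2001,289,458,352,288,2.6,565
2002,286,591,201,236,1.3,359
2003,201,807,204,201,1.7,384
2004,195,600,292,295,2.0,521
2005,345,799,215,198,1.5,224
2006,311,823,349,232,2.2,294
2007,349,691,381,504,1.2,342
2008,244,899,162,146,1.3,207
2009,268,692,309,276,1.6,326
2010,337,762,176,164,1.1,161
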