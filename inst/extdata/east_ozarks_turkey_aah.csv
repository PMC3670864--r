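year,juvenile_harvest,adult_harvest,effort,effort_se
1996,626,2703,6.9298,0.519
1997,596,1764,6.5852,0.442
1998,847,2855,6.5854,0.384
1999,1833,1716,7.1273,0.401
2000,767,4237,6.2601,0.34
2001,1580,2781,7.6457,0.448
2002,1388,3399,7.4921,0.462
2003,884,4287,6.935,0.409
2004,1046,3289,8.1414,0.984
2005,887,2877,8.2299,0.527
2006,829,3033,6.7334,0.431
2007,904,2077,8.0017,0.483
2008,501,3011,6.0511,0.381
2009,791,2429,6.7649,0.394
2010,840,2233,6.2808,0.344
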