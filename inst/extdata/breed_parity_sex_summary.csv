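breed,parity_class,calf_sex,n,pct_sb
AY,1,M,1450,8.62
AY,1,F,1643,8.64
AY,2,M,1328,4.21
AY,2,F,1462,5.60
AY,3,M,2234,6.80
AY,3,F,2289,6.64
GU,1,M,1752,8.84
GU,1,F,1969,9.64
GU,2,M,1751,5.19
GU,2,F,1746,6.24
GU,3,M,2722,4.99
GU,3,F,2501,6.11
MS,1,M,379,10.29
MS,1,F,398,6.53
MS,2,M,499,4.40
MS,2,F,523,4.58
MS,3,M,649,5.08
MS,3,F,574,5.22
BS,1,M,10003,6.48
BS,1,F,13116,5.31
BS,2,M,11235,4.11
BS,2,F,10957,3.90
BS,3,M,17831,4.62
BS,3,F,17252,4.77
JE,1,M,44150,7.57
JE,1,F,133816,5.36
JE,2,M,46351,3.17
JE,2,F,82175,2.85
JE,3,M,72784,3.58
JE,3,F,106328,3.32
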