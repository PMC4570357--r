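infant,walking_onset_days,visit,age_months,awake_hours,count_left,count_right,rate_left,rate_right
a,320,1,6,11.0,12899,14348,1173,1304
a,320,2,8,9.50,12695,11669,1336,1228
a,320,3,10,7.50,8067,9407,1076,1254
b,291,1,1,11.0,10039,10262,913,933
b,291,2,3,9.50,19056,21599,2006,2274
b,291,3,5,8.75,18604,18160,2126,2075
c,329,1,7,9.75,12158,12758,1247,1309
c,329,2,9,7.25,9236,9369,1274,1292
c,329,3,11,8.00,13570,11516,1696,1440
d,481,1,8,5.25,19448,18046,3704,3437
d,481,2,10,8.50,14527,19986,1709,2351
d,481,3,12,8.00,16868,15068,2109,1884
e,519,1,2,7.50,11553,12631,1540,1684
e,519,2,4,8.50,24168,25645,2843,3017
e,519,3,6,8.50,12974,13611,1526,1601
f,495,1,3,8.00,6502,6771,813,846
f,495,2,5,7.75,12963,15434,1673,1991
f,495,3,7,6.50,9403,10938,1447,1683
g,461,1,8,8.00,14854,18461,1857,2308
g,461,2,10,7.50,25904,26536,3454,3538
g,461,3,12,8.50,21224,19454,2497,2289
h,509,1,7,7.25,25371,26616,3499,3671
h,509,2,9,6.75,9864,11153,1461,1652
h,509,3,11,7.00,11836,11315,1691,1616
i,376,1,3,10.00,15371,16350,1537,1635
i,376,2,5,8.25,11321,10251,1372,1243
i,376,3,7,6.75,10076,10340,1493,1532
j,426,1,5,10.00,20137,20289,2014,2029
j,426,2,7,9.50,16116,15419,1696,1623
j,426,3,9,7.50,18893,17594,2519,2346
k,426,1,5,9.75,10928,13768,1121,1412
k,426,2,7,10.00,15511,16547,1551,1655
k,426,3,9,8.00,15684,15726,1961,1966
l,288,1,2,9.50,17494,22242,1841,2341
l,288,2,4,10.50,19862,20494,1892,1952
l,288,3,6,9.25,19722,18986,2132,2053
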