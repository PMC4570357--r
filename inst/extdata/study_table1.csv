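infant,visit,age_months,aims_raw,weight_kg,length_cm,head_circumference_cm
a,1,6,29,6.4,61.0,43.0
a,2,8,39,8.2,64.5,45.0
a,3,10,53,8.7,68.6,45.0
b,1,1,5,4.2,55.0,37.0
b,2,3,13,6.0,64.8,40.5
b,3,5,21,7.6,66.0,41.2
c,1,7,32,8.2,64.8,35.5
c,2,9,51,9.0,66.0,47.0
c,3,11,53,9.3,71.1,48.0
d,1,8,31,8.9,70.0,45.0
d,2,10,41,9.1,74.0,46.0
d,3,12,51,9.9,76.2,47.0
e,1,2,7,4.7,56.5,40.0
e,2,4,17,6.6,62.5,42.5
e,3,6,26,7.5,67.3,44.0
f,1,3,8,3.8,59.0,38.0
f,2,5,15,6.2,63.5,39.0
f,3,7,27,6.8,63.5,41.5
g,1,8,26,9.1,73.0,46.0
g,2,10,38,9.7,74.0,46.0
g,3,12,52,10.0,76.2,49.0
h,1,7,23,7.3,72.1,45.7
h,2,9,34,8.3,73.0,47.0
h,3,11,42,9.4,75.0,48.0
i,1,3,8,6.4,59.5,41.0
i,2,5,24,7.2,64.8,43.0
i,3,7,42,7.7,68.6,44.5
j,1,5,16,6.4,60.0,40.0
j,2,7,29,7.2,64.8,42.0
j,3,9,35,7.5,66.0,42.7
k,1,5,22,8.3,65.0,45.5
k,2,7,30,9.5,71.0,47.0
k,3,9,50,10.0,71.0,48.0
l,1,2,9,6.0,60.0,39.0
l,2,4,21,7.7,67.5,42.3
l,3,6,34,8.7,71.1,44.0
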