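code,hemiparesis,aspects,aetiology,comorbidities,mrs,ar2_abs
1,left,4,LAA,HT;D,2,25.8
2,right,10,LAA,HT,0,31.5
3,right,8,CE,HT;AF,0,19.7
4,right,9,SVO,HT,0,13.1
5,right,5,SUAe,HT;CHD;COPD,1,78.3
6,right,8,LAA,HT,3,83.2
7,left,7,SUAe,HT,3,32.6
8,left,4,LAA,HT,3,92.1
9,left,9,SVO,HT;COPD;CHD,4,82.4
10,left,6,CE,HT;CHD;HF;AF,6,79.8
11,right,8,LAA,HT,0,16.1
12,right,9,SUAe,HT,0,11.4
13,left,6,SUAe,,3,84.9
14,left,8,SUAe,HT,1,11.8
15,left,5,CE,HT;COPD;AF,5,77.2
16,right,10,CE,HT;AF,4,79.5
17,left,5,LAA,,4,77.6
18,left,8,CE,HT;AF,3,77.0
19,right,10,SVO,HT;D,0,11.1
20,left,6,LAA,HT,4,86.2
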