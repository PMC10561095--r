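source,target,weight
1,2,0.7117
1,3,0.3215
1,4,0.4431
1,5,0.6580
2,22,0.8179
2,23,0.3893
2,24,0.2132
2,25,0.8065
3,16,0.4333
3,17,0.8896
3,18,0.7086
3,19,0.0171
3,20,0.1932
3,21,0.8897
4,6,0.9380
4,7,0.6014
5,11,0.1752
5,12,0.1096
5,13,0.7432
5,14,0.2404
5,15,0.6849
8,22,0.8328
8,47,0.1397
8,48,0.7896
8,49,0.1932
8,50,0.4378
9,22,0.7266
10,22,0.3939
13,14,0.9448
23,35,0.7992
23,36,0.6164
23,37,0.2802
23,38,0.0652
23,39,0.8393
23,40,0.5297
24,31,0.9806
24,32,0.0496
24,33,0.9852
24,34,0.3359
25,26,0.9701
25,27,0.8291
25,28,0.6448
25,29,0.2832
25,30,0.5597
38,41,0.6088
38,42,0.0043
38,43,0.2152
38,44,0.5119
38,45,0.8964
38,46,0.6535
42,43,0.2537
48,49,0.8281
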