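source,target,weight
1,2,0.8147
1,3,0.2760
1,4,0.1622
1,5,0.4173
2,22,0.6433
2,23,0.9361
2,24,0.0596
2,25,0.3015
3,16,0.4299
3,17,0.9160
3,18,0.5822
3,19,0.7363
3,20,0.8507
3,21,0.6797
4,6,0.7943
4,7,0.0479
5,11,0.3789
5,12,0.5468
5,13,0.6802
5,14,0.7011
5,15,0.0942
8,22,0.5407
8,47,0.3947
8,48,0.5606
8,49,0.9448
8,50,0.3112
9,22,0.9027
10,22,0.0714
13,14,0.9448
23,35,0.6433
23,36,0.0376
23,37,0.8116
23,38,0.6663
23,39,0.5985
23,40,0.4624
24,31,0.8699
24,32,0.6834
24,33,0.9296
24,34,0.9457
25,26,0.5328
25,27,0.2316
25,28,0.0714
25,29,0.52391
25,30,0.4709
38,41,0.4243
38,42,0.2684
38,43,0.7040
38,44,0.6967
38,45,0.3507
38,46,0.4889
42,43,0.0516
48,49,0.6981
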