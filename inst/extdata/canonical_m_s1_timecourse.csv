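time_min,A,B,T
0,1,1,0.050438043
10,1.8275938,1.8275938,0.055309589
20,1.5707469,1.5707469,0.062055353
30,1.3806865,1.3806865,0.065428054
40,1.2468749,1.2468749,0.066562426
50,1.1566471,1.1566471,0.066322179
60,1.0978461,1.0978461,0.065315266
70,1.0604663,1.0604663,0.063940367
80,1.0371056,1.0371056,0.062442866
90,1.0226687,1.0226687,0.060964411
100,1.0138103,1.0138103,0.059580346
110,1.0083991,1.0083991,0.058325471
120,1.0051027,1.0051027,0.057210814
130,1.003098,1.003098,0.056234128
140,1.0018802,1.0018802,0.055386281
150,1.0011408,1.0011408,0.054655044
160,1.0006921,1.0006921,0.054027268
170,1.0004198,1.0004198,0.053490079
180,1.0002547,1.0002547,0.053031491
190,1.0001545,1.0001545,0.052640674
200,1.0000937,1.0000937,0.052308032
210,1.0000568,1.0000568,0.052025168
220,1.0000345,1.0000345,0.051784797
230,1.0000209,1.0000209,0.05158064
240,1.0000127,1.0000127,0.051407309
250,1.0000077,1.0000077,0.051260191
260,1.0000047,1.0000047,0.051135351
270,1.0000028,1.0000028,0.051029433
280,1.0000017,1.0000017,0.050939581
290,1.000001,1.000001,0.050863365
300,1.0000006,1.0000006,0.050798722
310,1.0000004,1.0000004,0.050743897
320,1.0000002,1.0000002,0.050697402
330,1.0000001,1.0000001,0.050657973
340,1.0000001,1.0000001,0.050624537
350,1.0000001,1.0000001,0.050596184
360,1,1,0.050572142
370,1,1,0.050551756
380,1,1,0.050534469
390,1,1,0.050519811
400,1,1,0.050507383
410,1,1,0.050496845
420,1,1,0.050487909
430,1,1,0.050480333
440,1,1,0.050473909
450,1,1,0.050468463
460,1,1,0.050463844
470,1,1,0.050459929
480,1,1,0.050456609
490,1,1,0.050453794
500,1,1,0.050451407
510,1,1,0.050449383
520,1,1,0.050447667
530,1,1,0.050446212
540,1,1,0.050444979
550,1,1,0.050443933
560,1,1,0.050443046
570,1,1,0.050442294
580,1,1,0.050441657
590,1,1,0.050441116
600,1,1,0.050440658
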