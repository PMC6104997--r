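x,y
3,0
3.3502,0.2931
3.6165,0.6377
3.7414,1.0025
3.6938,1.3444
3.4765,1.6211
3.1253,1.8044
2.6998,1.8904
2.2672,1.9024
1.886,1.886
1.5916,1.8968
1.3893,1.9842
1.2567,2.1766
1.1526,2.4718
1.032,2.8354
0.8598,3.2087
0.6212,3.523
0.3252,3.7167
0,3.75
-0.3163,3.6148
-0.5881,3.3354
-0.7936,2.9619
-0.931,2.558
-1.0195,2.1863
-1.0938,1.8945
-1.195,1.7067
-1.3591,1.6197
-1.6066,1.6066
-1.9361,1.6245
-2.3222,1.626
-2.7203,1.5706
-3.075,1.4339
-3.3325,1.2129
-3.4536,0.9254
-3.4239,0.6037
-3.2584,0.2851
-3,0
-2.71,-0.2371
-2.454,-0.4327
-2.2859,-0.6125
-2.2343,-0.8132
-2.2946,-1.07
-2.4308,-1.4034
-2.5846,-1.8098
-2.6912,-2.2582
-2.696,-2.696
-2.569,-3.0616
-2.3108,-3.3002
-1.9512,-3.3795
-1.5385,-3.2993
-1.1257,-3.0927
-0.7553,-2.8187
-0.4492,-2.5475
-0.205,-2.3436
0,-2.25
0.1994,-2.2793
0.4253,-2.4118
0.6972,-2.6019
1.0156,-2.7902
1.3608,-2.9183
1.6983,-2.9416
1.9877,-2.8387
2.1938,-2.6144
2.2966,-2.2966
2.2981,-1.9283
2.2232,-1.5567
2.1158,-1.2216
2.0296,-0.9464
2.0157,-0.7337
2.1101,-0.5654
2.3233,-0.4097
2.6357,-0.2306
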