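"x","y","z","value"
5,5,2,1.114803
6,5,2,1.036022
7,5,2,0.996016
8,5,2,1.084107
9,5,2,1.052958
5,6,2,1.101138
6,6,2,0.998195
7,6,2,1.076271
8,6,2,1.01834
9,6,2,1.147518
5,7,2,1.095258
6,7,2,1.004249
7,7,2,1.024229
8,7,2,0.99669
9,7,2,1.103823
5,8,2,1.021538
6,8,2,0.989225
7,8,2,1.039828
8,8,2,0.938433
9,8,2,0.976153
7,9,2,0.990599
8,9,2,1.022527
5,3,3,1.122621
6,3,3,1.133088
7,3,3,1.171497
8,3,3,1.072718
9,3,3,1.154605
4,4,3,1.221604
5,4,3,1.039617
6,4,3,1.142747
7,4,3,1.08514
8,4,3,1.091266
9,4,3,1.181189
10,4,3,1.10777
3,5,3,1.096321
4,5,3,1.070248
5,5,3,1.086562
6,5,3,0.991277
7,5,3,1.126739
8,5,3,1.169906
9,5,3,1.144723
10,5,3,1.118488
11,5,3,1.150911
3,6,3,1.008589
4,6,3,1.12103
5,6,3,1.039638
6,6,3,1.056989
7,6,3,1.054699
8,6,3,1.078091
9,6,3,1.079878
10,6,3,1.021911
11,6,3,1.081476
3,7,3,1.045596
4,7,3,1.006819
5,7,3,1.045776
6,7,3,1.081186
7,7,3,1.051305
8,7,3,1.121857
9,7,3,0.973232
10,7,3,1.050967
11,7,3,1.077426
3,8,3,1.042851
4,8,3,1.070435
5,8,3,0.992413
6,8,3,1.113775
7,8,3,1.041954
8,8,3,1.035261
9,8,3,0.988757
10,8,3,1.037732
11,8,3,1.029675
4,9,3,1.003866
5,9,3,0.992314
6,9,3,1.065641
7,9,3,1.05912
8,9,3,1.000437
9,9,3,0.930522
10,9,3,0.925784
11,9,3,1.114494
5,10,3,1.055805
6,10,3,0.984719
7,10,3,1.038941
8,10,3,0.955016
9,10,3,0.999804
6,2,4,1.082836
7,2,4,0.960199
8,2,4,1.180499
4,3,4,1.189028
5,3,4,1.19468
6,3,4,1.176939
7,3,4,1.138506
8,3,4,1.150261
9,3,4,1.064956
10,3,4,1.128567
3,4,4,1.10476
4,4,4,1.212212
5,4,4,1.125937
6,4,4,1.060489
7,4,4,1.142727
8,4,4,1.195134
9,4,4,1.091258
10,4,4,1.136385
11,4,4,1.119479
3,5,4,1.087976
4,5,4,1.087621
5,5,4,1.135063
6,5,4,1.138455
7,5,4,1.07959
8,5,4,1.059616
9,5,4,1.075012
10,5,4,1.148963
11,5,4,1.149296
12,5,4,1.121131
2,6,4,1.00525
3,6,4,1.022075
4,6,4,1.074279
5,6,4,1.057844
6,6,4,1.06982
7,6,4,1.05999
8,6,4,1.014569
9,6,4,1.041742
10,6,4,1.10783
11,6,4,1.085197
12,6,4,1.044775
13,6,4,1.161091
14,6,4,0.958231
2,7,4,1.025501
3,7,4,0.928102
4,7,4,1.142453
5,7,4,1.04897
6,7,4,0.993008
7,7,4,1.077297
8,7,4,1.083363
9,7,4,1.077146
10,7,4,1.020631
11,7,4,1.167334
12,7,4,1.005056
13,7,4,1.018968
14,7,4,1.043477
2,8,4,1.042319
3,8,4,0.982471
4,8,4,1.021505
5,8,4,1.073643
6,8,4,1.029843
7,8,4,0.994432
8,8,4,1.070102
9,8,4,1.080197
10,8,4,1.071092
11,8,4,1.018628
12,8,4,1.088596
3,9,4,1.032822
4,9,4,1.041324
5,9,4,0.940033
6,9,4,0.986503
7,9,4,1.087643
8,9,4,0.984538
9,9,4,0.989291
10,9,4,0.965334
11,9,4,0.999243
4,10,4,0.980909
5,10,4,0.999164
6,10,4,1.029193
7,10,4,0.979951
8,10,4,1.018188
9,10,4,1.000524
10,10,4,1.00732
5,11,4,0.995463
6,11,4,1.103086
7,11,4,1.08489
8,11,4,1.069563
9,11,4,1.008981
6,2,5,1.083516
7,2,5,1.157478
8,2,5,1.183509
4,3,5,1.192969
5,3,5,1.21948
6,3,5,1.065598
7,3,5,1.045715
8,3,5,1.180695
9,3,5,1.165871
10,3,5,1.107254
3,4,5,1.195797
4,4,5,1.088876
5,4,5,1.097208
6,4,5,1.14601
7,4,5,1.086568
8,4,5,1.205238
9,4,5,1.12681
10,4,5,1.097213
11,4,5,1.075234
3,5,5,1.045781
4,5,5,1.068167
5,5,5,1.158923
6,5,5,1.190027
7,5,5,1.062121
8,5,5,1.090494
9,5,5,1.00515
10,5,5,1.10388
11,5,5,1.105805
12,5,5,1.078126
2,6,5,1.083004
3,6,5,1.047318
4,6,5,1.131808
5,6,5,1.003612
6,6,5,1.058624
7,6,5,1.139774
8,6,5,1.034844
9,6,5,1.048464
10,6,5,1.090697
11,6,5,1.05746
12,6,5,1.080802
2,7,5,0.950099
3,7,5,0.987644
4,7,5,0.980872
5,7,5,1.105865
6,7,5,1.076865
7,7,5,1.146907
8,7,5,0.981208
9,7,5,1.102505
10,7,5,1.061468
11,7,5,1.034884
12,7,5,1.07807
3,8,5,0.986256
4,8,5,1.036106
5,8,5,0.964899
6,8,5,1.081294
7,8,5,1.068929
8,8,5,0.982503
9,8,5,1.056275
10,8,5,0.969485
11,8,5,1.082919
12,8,5,1.012445
3,9,5,0.953659
4,9,5,0.983493
5,9,5,1.031074
6,9,5,1.110041
7,9,5,0.942339
8,9,5,0.922402
9,9,5,0.982166
10,9,5,0.937191
11,9,5,0.901754
2,10,5,1.031808
4,10,5,0.949023
5,10,5,0.923973
6,10,5,1.029694
7,10,5,1.01834
8,10,5,0.939973
9,10,5,0.986268
10,10,5,0.949796
2,11,5,0.987164
6,11,5,1.032929
7,11,5,1.118378
8,11,5,0.960036
9,11,5,1.05774
2,12,5,1.026163
6,3,6,1.127603
7,3,6,1.169834
8,3,6,1.123626
5,4,6,1.190394
6,4,6,1.157741
7,4,6,1.169246
8,4,6,1.10895
9,4,6,1.092084
10,4,6,1.02268
4,5,6,1.16911
5,5,6,1.018677
6,5,6,1.154184
7,5,6,1.057119
8,5,6,1.08614
9,5,6,1.121245
10,5,6,1.13299
3,6,6,1.088303
4,6,6,1.023716
5,6,6,1.042041
6,6,6,1.058499
7,6,6,1.054875
8,6,6,1.175542
9,6,6,1.148568
10,6,6,1.132967
11,6,6,1.065912
3,7,6,1.064354
4,7,6,1.066654
5,7,6,1.016618
6,7,6,1.014651
7,7,6,1.043185
8,7,6,1.059438
9,7,6,1.093008
10,7,6,1.129886
11,7,6,1.02997
4,8,6,1.000638
5,8,6,0.955285
6,8,6,0.941667
7,8,6,1.132673
8,8,6,1.043991
9,8,6,1.097239
10,8,6,1.008117
11,8,6,1.080798
4,9,6,1.056958
5,9,6,1.093083
6,9,6,1.06305
7,9,6,1.002336
8,9,6,1.017212
9,9,6,1.108606
10,9,6,0.968013
2,10,6,0.993978
6,10,6,1.024639
7,10,6,1.113863
8,10,6,0.976766
2,11,6,1.025744
2,12,6,1.017628
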