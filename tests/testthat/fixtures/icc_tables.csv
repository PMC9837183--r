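"table","row","r1","r2"
1,1,5.988651,9.449094
1,2,12.722188,13.813213
1,3,11.61467,10.917101
1,4,12.377767,13.641073
1,5,10.652832,10.762992
1,6,12.86397,14.54728
1,7,7.24826,6.952515
1,8,9.516844,9.400227
1,9,10.519808,11.196906
1,10,15.222996,17.594347
1,11,1.178964,-0.781531
1,12,8.740261,9.272799
1,13,8.868294,10.750155
1,14,9.610706,10.810663
1,15,11.724117,10.957912
1,16,11.616113,15.792919
1,17,12.118575,13.253364
1,18,16.98922,16.897923
1,19,10.852391,7.594911
1,20,13.288371,14.61874
1,21,7.932345,10.864552
1,22,15.445232,14.958428
1,23,17.679777,15.088519
1,24,7.866631,7.622875
1,25,3.144371,5.772782
1,26,8.37619,11.618631
1,27,7.735227,8.569186
1,28,4.818762,7.347275
1,29,17.070471,15.988088
1,30,12.622722,11.105693
2,1,13.38113,14.302256
2,2,14.034647,13.022719
2,3,8.707444,10.836564
2,4,1.369734,0.827643
2,5,3.610891,7.624999
2,6,10.903428,13.721871
2,7,9.629474,8.884438
2,8,13.444831,9.962166
2,9,17.533361,17.194825
2,10,10.682634,11.260377
2,11,6.611942,8.098789
2,12,4.964841,5.303716
2,13,9.190683,10.313739
2,14,7.231726,7.237402
2,15,5.035674,3.787806
2,16,9.558014,9.540405
2,17,11.592125,10.13822
2,18,13.643907,12.730819
2,19,9.34015,7.372719
2,20,9.983219,9.90884
2,21,11.534257,12.009776
2,22,8.660235,11.963759
2,23,6.901156,7.06627
2,24,9.032463,7.042192
2,25,9.572308,9.133583
2,26,8.956449,8.847228
2,27,7.744355,7.592039
2,28,12.555869,12.870897
2,29,8.875954,6.712842
2,30,14.193123,12.246905
3,1,8.554456,9.212693
3,2,12.541724,13.11442
3,3,3.805802,4.666012
3,4,10.952023,10.531545
3,5,9.867876,12.076258
3,6,15.432385,12.31049
3,7,13.724745,13.440977
3,8,11.267476,9.133777
3,9,9.755546,11.217302
3,10,8.400445,8.464385
3,11,12.982978,13.986083
3,12,7.323491,10.885325
3,13,12.74014,13.585213
3,14,8.723606,8.597377
3,15,11.68757,11.968213
3,16,8.777936,9.851404
3,17,5.084654,6.125536
3,18,10.810176,11.431964
3,19,8.9302,10.816317
3,20,10.672827,13.012952
3,21,6.297857,8.428323
3,22,10.594699,10.356762
3,23,11.885038,12.059605
3,24,7.802407,8.314869
3,25,8.957001,10.021345
3,26,12.978385,14.40162
3,27,11.58707,14.835676
3,28,12.4672,13.665027
3,29,12.138117,12.735983
3,30,11.708257,9.989198
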