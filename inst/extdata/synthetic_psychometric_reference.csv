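participant_id,condition,level,n_trials,n_positive
synth01,push_away,-20,8000,0
synth01,push_away,-10,8000,0
synth01,push_away,-6,8000,0
synth01,push_away,-3.6,8000,32
synth01,push_away,-1.2,8000,1304
synth01,push_away,1.2,8000,6027
synth01,push_away,3.6,8000,7925
synth01,push_away,6,8000,8000
synth01,push_away,10,8000,8000
synth01,push_away,20,8000,8000
synth02,push_away,-20,8000,0
synth02,push_away,-10,8000,0
synth02,push_away,-6,8000,61
synth02,push_away,-3.6,8000,488
synth02,push_away,-1.2,8000,2025
synth02,push_away,1.2,8000,4686
synth02,push_away,3.6,8000,6912
synth02,push_away,6,8000,7809
synth02,push_away,10,8000,7998
synth02,push_away,20,8000,8000
synth03,push_away,-20,8000,0
synth03,push_away,-10,8000,24
synth03,push_away,-6,8000,321
synth03,push_away,-3.6,8000,1001
synth03,push_away,-1.2,8000,2327
synth03,push_away,1.2,8000,4155
synth03,push_away,3.6,8000,5931
synth03,push_away,6,8000,7150
synth03,push_away,10,8000,7901
synth03,push_away,20,8000,8000
synth04,push_away,-20,8000,0
synth04,push_away,-10,8000,124
synth04,push_away,-6,8000,647
synth04,push_away,-3.6,8000,1377
synth04,push_away,-1.2,8000,2491
synth04,push_away,1.2,8000,3878
synth04,push_away,3.6,8000,5289
synth04,push_away,6,8000,6461
synth04,push_away,10,8000,7584
synth04,push_away,20,8000,7998
synth05,push_away,-20,8000,4
synth05,push_away,-10,8000,290
synth05,push_away,-6,8000,942
synth05,push_away,-3.6,8000,1646
synth05,push_away,-1.2,8000,2593
synth05,push_away,1.2,8000,3710
synth05,push_away,3.6,8000,4864
synth05,push_away,6,8000,5910
synth05,push_away,10,8000,7152
synth05,push_away,20,8000,7978
synth06,push_away,-20,8000,19
synth06,push_away,-10,8000,482
synth06,push_away,-6,8000,1188
synth06,push_away,-3.6,8000,1843
synth06,push_away,-1.2,8000,2663
synth06,push_away,1.2,8000,3597
synth06,push_away,3.6,8000,4568
synth06,push_away,6,8000,5488
synth06,push_away,10,8000,6719
synth06,push_away,20,8000,7906
synth07,push_away,-20,8000,54
synth07,push_away,-10,8000,673
synth07,push_away,-6,8000,1389
synth07,push_away,-3.6,8000,1993
synth07,push_away,-1.2,8000,2713
synth07,push_away,1.2,8000,3516
synth07,push_away,3.6,8000,4352
synth07,push_away,6,8000,5164
synth07,push_away,10,8000,6330
synth07,push_away,20,8000,7773
synth08,push_away,-20,8000,110
synth08,push_away,-10,8000,851
synth08,push_away,-6,8000,1554
synth08,push_away,-3.6,8000,2110
synth08,push_away,-1.2,8000,2752
synth08,push_away,1.2,8000,3456
synth08,push_away,3.6,8000,4188
synth08,push_away,6,8000,4910
synth08,push_away,10,8000,5996
synth08,push_away,20,8000,7590
synth01,pull_toward,-20,8000,0
synth01,pull_toward,-10,8000,0
synth01,pull_toward,-6,8000,0
synth01,pull_toward,-3.6,8000,0
synth01,pull_toward,-1.2,8000,1825
synth01,pull_toward,1.2,8000,8000
synth01,pull_toward,3.6,8000,8000
synth01,pull_toward,6,8000,8000
synth01,pull_toward,10,8000,8000
synth01,pull_toward,20,8000,8000
synth02,pull_toward,-20,8000,0
synth02,pull_toward,-10,8000,0
synth02,pull_toward,-6,8000,64
synth02,pull_toward,-3.6,8000,681
synth02,pull_toward,-1.2,8000,2957
synth02,pull_toward,1.2,8000,6079
synth02,pull_toward,3.6,8000,7676
synth02,pull_toward,6,8000,7978
synth02,pull_toward,10,8000,8000
synth02,pull_toward,20,8000,8000
synth03,pull_toward,-20,8000,0
synth03,pull_toward,-10,8000,84
synth03,pull_toward,-6,8000,644
synth03,pull_toward,-3.6,8000,1565
synth03,pull_toward,-1.2,8000,3017
synth03,pull_toward,1.2,8000,4730
synth03,pull_toward,3.6,8000,6247
synth03,pull_toward,6,8000,7252
synth03,pull_toward,10,8000,7896
synth03,pull_toward,20,8000,8000
synth04,pull_toward,-20,8000,6
synth04,pull_toward,-10,8000,389
synth04,pull_toward,-6,8000,1187
synth04,pull_toward,-3.6,8000,1999
synth04,pull_toward,-1.2,8000,3038
synth04,pull_toward,1.2,8000,4199
synth04,pull_toward,3.6,8000,5334
synth04,pull_toward,6,8000,6304
synth04,pull_toward,10,8000,7370
synth04,pull_toward,20,8000,7987
synth05,pull_toward,-20,8000,52
synth05,pull_toward,-10,8000,741
synth05,pull_toward,-6,8000,1559
synth05,pull_toward,-3.6,8000,2244
synth05,pull_toward,-1.2,8000,3049
synth05,pull_toward,1.2,8000,3924
synth05,pull_toward,3.6,8000,4804
synth05,pull_toward,6,8000,5625
synth05,pull_toward,10,8000,6727
synth05,pull_toward,20,8000,7877
synth06,pull_toward,-20,8000,159
synth06,pull_toward,-10,8000,1047
synth06,pull_toward,-6,8000,1816
synth06,pull_toward,-3.6,8000,2400
synth06,pull_toward,-1.2,8000,3055
synth06,pull_toward,1.2,8000,3756
synth06,pull_toward,3.6,8000,4469
synth06,pull_toward,6,8000,5160
synth06,pull_toward,10,8000,6175
synth06,pull_toward,20,8000,7627
synth07,pull_toward,-20,8000,309
synth07,pull_toward,-10,8000,1297
synth07,pull_toward,-6,8000,2002
synth07,pull_toward,-3.6,8000,2507
synth07,pull_toward,-1.2,8000,3060
synth07,pull_toward,1.2,8000,3644
synth07,pull_toward,3.6,8000,4241
synth07,pull_toward,6,8000,4830
synth07,pull_toward,10,8000,5739
synth07,pull_toward,20,8000,7299
synth08,pull_toward,-20,8000,476
synth08,pull_toward,-10,8000,1498
synth08,pull_toward,-6,8000,2141
synth08,pull_toward,-3.6,8000,2585
synth08,pull_toward,-1.2,8000,3063
synth08,pull_toward,1.2,8000,3564
synth08,pull_toward,3.6,8000,4076
synth08,pull_toward,6,8000,4587
synth08,pull_toward,10,8000,5398
synth08,pull_toward,20,8000,6955
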