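participant_id,condition,level,n_trials,n_positive
synth01,push_away,-20,8000,11
synth01,push_away,-10,8000,164
synth01,push_away,-6,8000,408
synth01,push_away,-3.6,8000,671
synth01,push_away,-1.2,8000,1064
synth01,push_away,1.2,8000,1619
synth01,push_away,3.6,8000,2356
synth01,push_away,6,8000,3264
synth01,push_away,10,8000,4967
synth01,push_away,20,8000,7647
synth02,push_away,-20,8000,11
synth02,push_away,-10,8000,164
synth02,push_away,-6,8000,408
synth02,push_away,-3.6,8000,671
synth02,push_away,-1.2,8000,1064
synth02,push_away,1.2,8000,1619
synth02,push_away,3.6,8000,2356
synth02,push_away,6,8000,3264
synth02,push_away,10,8000,4967
synth02,push_away,20,8000,7647
synth03,push_away,-20,8000,11
synth03,push_away,-10,8000,164
synth03,push_away,-6,8000,408
synth03,push_away,-3.6,8000,671
synth03,push_away,-1.2,8000,1064
synth03,push_away,1.2,8000,1619
synth03,push_away,3.6,8000,2356
synth03,push_away,6,8000,3264
synth03,push_away,10,8000,4967
synth03,push_away,20,8000,7647
synth04,push_away,-20,8000,11
synth04,push_away,-10,8000,164
synth04,push_away,-6,8000,408
synth04,push_away,-3.6,8000,671
synth04,push_away,-1.2,8000,1064
synth04,push_away,1.2,8000,1619
synth04,push_away,3.6,8000,2356
synth04,push_away,6,8000,3264
synth04,push_away,10,8000,4967
synth04,push_away,20,8000,7647
synth05,push_away,-20,8000,11
synth05,push_away,-10,8000,164
synth05,push_away,-6,8000,408
synth05,push_away,-3.6,8000,671
synth05,push_away,-1.2,8000,1064
synth05,push_away,1.2,8000,1619
synth05,push_away,3.6,8000,2356
synth05,push_away,6,8000,3264
synth05,push_away,10,8000,4967
synth05,push_away,20,8000,7647
synth06,push_away,-20,8000,11
synth06,push_away,-10,8000,164
synth06,push_away,-6,8000,408
synth06,push_away,-3.6,8000,671
synth06,push_away,-1.2,8000,1064
synth06,push_away,1.2,8000,1619
synth06,push_away,3.6,8000,2356
synth06,push_away,6,8000,3264
synth06,push_away,10,8000,4967
synth06,push_away,20,8000,7647
synth07,push_away,-20,8000,11
synth07,push_away,-10,8000,164
synth07,push_away,-6,8000,408
synth07,push_away,-3.6,8000,671
synth07,push_away,-1.2,8000,1064
synth07,push_away,1.2,8000,1619
synth07,push_away,3.6,8000,2356
synth07,push_away,6,8000,3264
synth07,push_away,10,8000,4967
synth07,push_away,20,8000,7647
synth08,push_away,-20,8000,11
synth08,push_away,-10,8000,164
synth08,push_away,-6,8000,408
synth08,push_away,-3.6,8000,671
synth08,push_away,-1.2,8000,1064
synth08,push_away,1.2,8000,1619
synth08,push_away,3.6,8000,2356
synth08,push_away,6,8000,3264
synth08,push_away,10,8000,4967
synth08,push_away,20,8000,7647
synth01,pull_toward,-20,8000,353
synth01,pull_toward,-10,8000,3033
synth01,pull_toward,-6,8000,4736
synth01,pull_toward,-3.6,8000,5644
synth01,pull_toward,-1.2,8000,6381
synth01,pull_toward,1.2,8000,6936
synth01,pull_toward,3.6,8000,7329
synth01,pull_toward,6,8000,7592
synth01,pull_toward,10,8000,7836
synth01,pull_toward,20,8000,7989
synth02,pull_toward,-20,8000,353
synth02,pull_toward,-10,8000,3033
synth02,pull_toward,-6,8000,4736
synth02,pull_toward,-3.6,8000,5644
synth02,pull_toward,-1.2,8000,6381
synth02,pull_toward,1.2,8000,6936
synth02,pull_toward,3.6,8000,7329
synth02,pull_toward,6,8000,7592
synth02,pull_toward,10,8000,7836
synth02,pull_toward,20,8000,7989
synth03,pull_toward,-20,8000,353
synth03,pull_toward,-10,8000,3033
synth03,pull_toward,-6,8000,4736
synth03,pull_toward,-3.6,8000,5644
synth03,pull_toward,-1.2,8000,6381
synth03,pull_toward,1.2,8000,6936
synth03,pull_toward,3.6,8000,7329
synth03,pull_toward,6,8000,7592
synth03,pull_toward,10,8000,7836
synth03,pull_toward,20,8000,7989
synth04,pull_toward,-20,8000,353
synth04,pull_toward,-10,8000,3033
synth04,pull_toward,-6,8000,4736
synth04,pull_toward,-3.6,8000,5644
synth04,pull_toward,-1.2,8000,6381
synth04,pull_toward,1.2,8000,6936
synth04,pull_toward,3.6,8000,7329
synth04,pull_toward,6,8000,7592
synth04,pull_toward,10,8000,7836
synth04,pull_toward,20,8000,7989
synth05,pull_toward,-20,8000,353
synth05,pull_toward,-10,8000,3033
synth05,pull_toward,-6,8000,4736
synth05,pull_toward,-3.6,8000,5644
synth05,pull_toward,-1.2,8000,6381
synth05,pull_toward,1.2,8000,6936
synth05,pull_toward,3.6,8000,7329
synth05,pull_toward,6,8000,7592
synth05,pull_toward,10,8000,7836
synth05,pull_toward,20,8000,7989
synth06,pull_toward,-20,8000,353
synth06,pull_toward,-10,8000,3033
synth06,pull_toward,-6,8000,4736
synth06,pull_toward,-3.6,8000,5644
synth06,pull_toward,-1.2,8000,6381
synth06,pull_toward,1.2,8000,6936
synth06,pull_toward,3.6,8000,7329
synth06,pull_toward,6,8000,7592
synth06,pull_toward,10,8000,7836
synth06,pull_toward,20,8000,7989
synth07,pull_toward,-20,8000,353
synth07,pull_toward,-10,8000,3033
synth07,pull_toward,-6,8000,4736
synth07,pull_toward,-3.6,8000,5644
synth07,pull_toward,-1.2,8000,6381
synth07,pull_toward,1.2,8000,6936
synth07,pull_toward,3.6,8000,7329
synth07,pull_toward,6,8000,7592
synth07,pull_toward,10,8000,7836
synth07,pull_toward,20,8000,7989
synth08,pull_toward,-20,8000,353
synth08,pull_toward,-10,8000,3033
synth08,pull_toward,-6,8000,4736
synth08,pull_toward,-3.6,8000,5644
synth08,pull_toward,-1.2,8000,6381
synth08,pull_toward,1.2,8000,6936
synth08,pull_toward,3.6,8000,7329
synth08,pull_toward,6,8000,7592
synth08,pull_toward,10,8000,7836
synth08,pull_toward,20,8000,7989
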