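participant_id,condition,level,n_trials,n_positive
synth01,push_away,-20,8000,11
synth01,push_away,-10,8000,220
synth01,push_away,-6,8000,650
synth01,push_away,-3.6,8000,1166
synth01,push_away,-1.2,8000,1947
synth01,push_away,1.2,8000,2978
synth01,push_away,3.6,8000,4138
synth01,push_away,6,8000,5249
synth01,push_away,10,8000,6657
synth01,push_away,20,8000,7887
synth02,push_away,-20,8000,11
synth02,push_away,-10,8000,220
synth02,push_away,-6,8000,650
synth02,push_away,-3.6,8000,1166
synth02,push_away,-1.2,8000,1947
synth02,push_away,1.2,8000,2978
synth02,push_away,3.6,8000,4138
synth02,push_away,6,8000,5249
synth02,push_away,10,8000,6657
synth02,push_away,20,8000,7887
synth03,push_away,-20,8000,11
synth03,push_away,-10,8000,220
synth03,push_away,-6,8000,650
synth03,push_away,-3.6,8000,1166
synth03,push_away,-1.2,8000,1947
synth03,push_away,1.2,8000,2978
synth03,push_away,3.6,8000,4138
synth03,push_away,6,8000,5249
synth03,push_away,10,8000,6657
synth03,push_away,20,8000,7887
synth04,push_away,-20,8000,11
synth04,push_away,-10,8000,220
synth04,push_away,-6,8000,650
synth04,push_away,-3.6,8000,1166
synth04,push_away,-1.2,8000,1947
synth04,push_away,1.2,8000,2978
synth04,push_away,3.6,8000,4138
synth04,push_away,6,8000,5249
synth04,push_away,10,8000,6657
synth04,push_away,20,8000,7887
synth05,push_away,-20,8000,11
synth05,push_away,-10,8000,220
synth05,push_away,-6,8000,650
synth05,push_away,-3.6,8000,1166
synth05,push_away,-1.2,8000,1947
synth05,push_away,1.2,8000,2978
synth05,push_away,3.6,8000,4138
synth05,push_away,6,8000,5249
synth05,push_away,10,8000,6657
synth05,push_away,20,8000,7887
synth06,push_away,-20,8000,11
synth06,push_away,-10,8000,220
synth06,push_away,-6,8000,650
synth06,push_away,-3.6,8000,1166
synth06,push_away,-1.2,8000,1947
synth06,push_away,1.2,8000,2978
synth06,push_away,3.6,8000,4138
synth06,push_away,6,8000,5249
synth06,push_away,10,8000,6657
synth06,push_away,20,8000,7887
synth07,push_away,-20,8000,11
synth07,push_away,-10,8000,220
synth07,push_away,-6,8000,650
synth07,push_away,-3.6,8000,1166
synth07,push_away,-1.2,8000,1947
synth07,push_away,1.2,8000,2978
synth07,push_away,3.6,8000,4138
synth07,push_away,6,8000,5249
synth07,push_away,10,8000,6657
synth07,push_away,20,8000,7887
synth08,push_away,-20,8000,11
synth08,push_away,-10,8000,220
synth08,push_away,-6,8000,650
synth08,push_away,-3.6,8000,1166
synth08,push_away,-1.2,8000,1947
synth08,push_away,1.2,8000,2978
synth08,push_away,3.6,8000,4138
synth08,push_away,6,8000,5249
synth08,push_away,10,8000,6657
synth08,push_away,20,8000,7887
synth01,pull_toward,-20,8000,113
synth01,pull_toward,-10,8000,1343
synth01,pull_toward,-6,8000,2751
synth01,pull_toward,-3.6,8000,3862
synth01,pull_toward,-1.2,8000,5022
synth01,pull_toward,1.2,8000,6053
synth01,pull_toward,3.6,8000,6834
synth01,pull_toward,6,8000,7350
synth01,pull_toward,10,8000,7780
synth01,pull_toward,20,8000,7989
synth02,pull_toward,-20,8000,113
synth02,pull_toward,-10,8000,1343
synth02,pull_toward,-6,8000,2751
synth02,pull_toward,-3.6,8000,3862
synth02,pull_toward,-1.2,8000,5022
synth02,pull_toward,1.2,8000,6053
synth02,pull_toward,3.6,8000,6834
synth02,pull_toward,6,8000,7350
synth02,pull_toward,10,8000,7780
synth02,pull_toward,20,8000,7989
synth03,pull_toward,-20,8000,113
synth03,pull_toward,-10,8000,1343
synth03,pull_toward,-6,8000,2751
synth03,pull_toward,-3.6,8000,3862
synth03,pull_toward,-1.2,8000,5022
synth03,pull_toward,1.2,8000,6053
synth03,pull_toward,3.6,8000,6834
synth03,pull_toward,6,8000,7350
synth03,pull_toward,10,8000,7780
synth03,pull_toward,20,8000,7989
synth04,pull_toward,-20,8000,113
synth04,pull_toward,-10,8000,1343
synth04,pull_toward,-6,8000,2751
synth04,pull_toward,-3.6,8000,3862
synth04,pull_toward,-1.2,8000,5022
synth04,pull_toward,1.2,8000,6053
synth04,pull_toward,3.6,8000,6834
synth04,pull_toward,6,8000,7350
synth04,pull_toward,10,8000,7780
synth04,pull_toward,20,8000,7989
synth05,pull_toward,-20,8000,113
synth05,pull_toward,-10,8000,1343
synth05,pull_toward,-6,8000,2751
synth05,pull_toward,-3.6,8000,3862
synth05,pull_toward,-1.2,8000,5022
synth05,pull_toward,1.2,8000,6053
synth05,pull_toward,3.6,8000,6834
synth05,pull_toward,6,8000,7350
synth05,pull_toward,10,8000,7780
synth05,pull_toward,20,8000,7989
synth06,pull_toward,-20,8000,113
synth06,pull_toward,-10,8000,1343
synth06,pull_toward,-6,8000,2751
synth06,pull_toward,-3.6,8000,3862
synth06,pull_toward,-1.2,8000,5022
synth06,pull_toward,1.2,8000,6053
synth06,pull_toward,3.6,8000,6834
synth06,pull_toward,6,8000,7350
synth06,pull_toward,10,8000,7780
synth06,pull_toward,20,8000,7989
synth07,pull_toward,-20,8000,113
synth07,pull_toward,-10,8000,1343
synth07,pull_toward,-6,8000,2751
synth07,pull_toward,-3.6,8000,3862
synth07,pull_toward,-1.2,8000,5022
synth07,pull_toward,1.2,8000,6053
synth07,pull_toward,3.6,8000,6834
synth07,pull_toward,6,8000,7350
synth07,pull_toward,10,8000,7780
synth07,pull_toward,20,8000,7989
synth08,pull_toward,-20,8000,113
synth08,pull_toward,-10,8000,1343
synth08,pull_toward,-6,8000,2751
synth08,pull_toward,-3.6,8000,3862
synth08,pull_toward,-1.2,8000,5022
synth08,pull_toward,1.2,8000,6053
synth08,pull_toward,3.6,8000,6834
synth08,pull_toward,6,8000,7350
synth08,pull_toward,10,8000,7780
synth08,pull_toward,20,8000,7989
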