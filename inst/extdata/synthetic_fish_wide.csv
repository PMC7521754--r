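"fish_id","status","site","capture_year","age_at_capture","length_capture","radius_capture","r1","r2","r3","r4","r5"
"MR0001","MR","MR1",2015,2,59.7161,0.9463,0.6021,0.9012,,,
"MR0002","MR","MR2",2015,3,55.6887,0.8489,0.3822,0.6003,0.8085,,
"MR0003","MR","MR3",2015,4,92.2825,1.5467,0.5988,0.923,1.237,1.4731,
"MR0004","MR","MR4",2015,5,80.6756,1.3409,0.4465,0.6823,0.9178,1.1171,1.277
"FR0005","FR","FR1",2015,2,56.7522,0.8691,0.5332,0.8277,,,
"FR0006","FR","FR2",2015,3,63.1641,1.0297,0.5229,0.7712,0.9807,,
"FR0007","FR","FR3",2015,4,72.7408,1.1679,0.4957,0.7462,0.9489,1.1123,
"FR0008","FR","FR4",2015,5,61.8217,1.016,0.3621,0.5628,0.7338,0.8623,0.9676
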