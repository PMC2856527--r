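panelist_id,occasion,Q2,Q3,D1,D2,I1,I2,I3,I4,I5,I6,I7,E1,E2,E3
p01,test,0,2,1,1,1,1,1,0,1,1,2,0,3,2
p02,test,1,0,2,0,1,0,2,2,2,2,2,2,2,2
p03,test,2,2,2,2,2,2,2,1,2,1,1,1,0,0
p04,test,1,2,0,2,1,1,1,1,0,1,2,1,0,1
p05,test,1,1,1,3,2,0,1,2,1,2,2,1,0,1
p06,test,2,1,1,2,1,2,3,1,1,1,1,1,1,1
p07,test,1,2,2,1,3,0,1,3,0,1,1,2,1,2
p08,test,0,1,1,3,2,1,0,0,1,1,1,3,2,2
p09,test,2,2,2,2,2,2,2,2,2,2,2,2,2,2
p01,retest,0,3,1,1,2,2,2,1,1,0,2,0,3,1
p02,retest,0,0,3,0,1,1,2,2,3,1,2,2,3,0
p03,retest,1,2,2,3,2,1,3,2,3,0,2,1,0,2
p04,retest,2,3,1,2,1,1,1,1,0,2,2,0,0,0
p05,retest,1,1,1,3,1,0,0,2,1,1,2,0,0,1
p06,retest,3,1,1,2,1,1,3,1,1,1,1,2,1,1
p07,retest,1,2,2,1,3,0,1,3,0,0,2,3,0,2
p08,retest,1,1,1,3,2,1,0,0,1,1,0,3,2,1
p09,retest,2,2,2,2,2,1,1,1,1,0,0,0,1,1
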