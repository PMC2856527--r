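panelist_id,occasion,Q1,Q2,Q3,D1,D2,I1,I2,I3,I4,I5,I6,I7,E1,E2,E3
p01,test,5,4,5,4,3,4,4,5,5,4,5,4,4,2,4
p02,test,3,4,3,4,4,5,4,5,3,4,4,3,5,4,4
p03,test,5,4,4,4,4,5,5,4,3,4,4,5,3,5,4
p04,test,4,5,2,4,3,5,3,4,4,5,2,2,3,5,5
p05,test,5,4,4,4,4,5,4,5,2,3,4,3,4,5,4
p06,test,3,2,3,3,5,3,4,3,3,4,4,4,5,4,3
p07,test,3,4,3,4,3,5,5,3,4,5,3,5,5,3,4
p08,test,5,3,3,3,2,5,4,4,3,4,4,4,3,4,4
p09,test,3,3,3,3,3,3,3,3,3,3,3,3,3,2,2
p01,retest,5,4,5,4,3,4,4,4,5,4,5,4,5,4,2
p02,retest,2,4,2,5,4,5,5,5,5,4,5,2,5,3,4
p03,retest,5,4,3,3,4,5,3,4,4,5,5,5,3,5,4
p04,retest,5,4,2,4,3,5,2,5,3,5,2,2,4,5,4
p05,retest,5,4,4,4,4,5,4,5,4,3,4,3,5,5,5
p06,retest,3,2,4,2,5,4,5,2,5,4,4,3,5,2,3
p07,retest,4,3,4,5,3,5,4,2,3,4,3,3,5,4,4
p08,retest,5,2,2,2,2,5,4,2,2,3,4,4,5,5,3
p09,retest,3,3,3,3,3,3,3,3,3,3,3,3,3,2,2
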