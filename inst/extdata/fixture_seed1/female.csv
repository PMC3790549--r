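taxon,patch01,patch02,patch03,patch04,patch05,patch06,patch07,patch08,patch09,patch10,patch11,patch12,patch13,patch14,patch15,patch16,patch17,patch18,patch19,patch20,patch21,patch22,patch23,patch24,patch25,trait01,trait02,trait03,trait04,trait05
t01,W,B,D,D,C,B,D,W,N,W,B,L,D,C,N,W,C,D,B,L,L,L,B,N,C,P,P,A,A,P
t02,D,B,B,C,C,D,C,C,N,B,B,L,L,D,N,D,N,W,L,L,D,C,B,N,L,P,A,A,A,P
t03,B,B,B,L,D,D,C,C,D,L,B,L,L,N,D,D,N,C,L,W,L,C,W,W,L,P,A,A,A,A
t04,D,N,L,C,N,D,C,C,N,L,L,L,L,D,D,D,C,W,N,B,L,C,W,C,L,P,P,P,A,A
t05,B,B,N,D,N,D,W,C,N,L,L,D,D,W,N,D,C,D,B,W,L,L,B,C,C,P,P,A,A,A
t06,D,N,W,D,C,D,C,C,D,B,B,L,L,D,D,W,N,N,L,B,D,C,B,N,C,A,A,A,A,P
t07,D,N,B,C,N,D,B,D,D,B,B,W,L,D,N,D,N,C,B,W,D,C,W,D,L,P,P,A,A,A
t08,D,N,B,D,C,D,C,C,D,B,B,L,L,N,D,D,C,C,L,L,L,C,W,W,L,P,P,A,A,A
t09,B,B,W,D,W,D,C,C,D,B,B,L,L,N,N,D,N,C,L,B,D,C,B,N,L,P,A,A,A,A
t10,B,B,W,D,C,D,W,C,N,B,B,N,D,N,N,W,C,C,B,W,L,L,W,C,C,P,A,A,A,P
t11,B,B,W,D,C,D,W,C,N,B,B,N,D,N,N,L,C,C,N,W,L,L,N,W,C,P,P,A,A,P
t12,B,B,W,D,N,D,W,C,N,L,L,D,D,N,N,D,C,C,B,W,L,W,B,C,C,P,P,A,A,P
t13,W,B,D,D,C,C,B,D,N,L,B,L,D,C,N,W,B,D,B,L,L,L,L,C,C,P,P,A,A,P
t14,D,B,B,C,D,D,B,C,N,B,B,L,L,N,D,D,C,D,D,B,D,C,B,N,L,P,P,A,A,A
t15,W,N,B,C,C,D,C,W,N,W,B,L,N,D,D,D,N,D,B,L,L,C,W,N,C,P,A,A,A,A
t16,B,B,W,B,N,D,B,C,N,L,L,D,D,N,N,D,C,C,B,W,L,L,B,C,C,P,A,A,A,P
t17,B,N,W,C,D,D,C,C,D,B,B,N,L,D,D,D,C,C,D,B,L,L,W,N,L,P,A,A,A,A
t18,B,N,W,B,N,D,B,C,N,B,B,L,D,N,N,W,C,C,D,W,C,L,W,C,W,P,P,P,A,P
t19,D,N,B,C,D,D,C,C,D,B,B,L,L,D,N,D,N,W,L,W,C,L,W,N,L,P,P,A,A,P
t20,B,N,W,C,D,D,C,D,N,B,D,L,D,D,N,D,C,W,L,B,L,C,B,N,C,P,A,A,A,A
t21,B,B,B,D,D,D,C,C,B,B,L,L,L,D,N,D,N,W,L,W,L,C,W,N,L,P,A,A,A,A
t22,B,N,W,C,D,N,C,C,D,B,B,L,L,D,D,D,C,W,B,B,L,L,W,N,C,P,A,A,A,A
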