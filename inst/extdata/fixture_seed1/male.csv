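taxon,patch01,patch02,patch03,patch04,patch05,patch06,patch07,patch08,patch09,patch10,patch11,patch12,patch13,patch14,patch15,patch16,patch17,patch18,patch19,patch20,patch21,patch22,patch23,patch24,patch25,trait01,trait02,trait03,trait04,trait05
t01,W,B,D,D,C,B,D,W,N,W,B,L,D,C,N,W,C,D,B,L,L,L,B,N,C,P,P,A,A,P
t02,B,B,W,D,C,D,B,C,N,L,L,D,D,N,N,D,C,C,L,L,L,L,B,W,C,P,P,A,A,P
t03,B,B,W,L,C,D,B,C,N,L,L,D,D,N,N,D,C,C,L,L,L,L,B,W,C,P,P,A,A,P
t04,B,N,L,D,N,D,B,D,N,L,L,W,D,N,N,D,C,C,B,W,L,L,B,C,C,P,P,A,A,P
t05,B,B,W,D,N,D,W,C,N,L,L,D,D,N,N,D,C,C,B,W,L,L,B,C,C,P,P,A,A,P
t06,B,B,W,D,C,D,B,C,N,B,B,N,C,N,N,W,C,N,D,W,L,L,B,W,C,A,P,A,A,P
t07,B,N,W,D,N,D,B,D,N,L,L,W,D,N,N,D,C,C,B,W,L,L,B,C,C,P,P,A,A,P
t08,B,B,W,D,C,D,B,C,N,L,L,D,C,N,N,D,C,C,L,L,L,L,B,W,C,P,P,A,A,P
t09,B,B,W,D,W,D,B,C,N,B,B,N,D,N,N,W,C,C,D,W,L,L,B,N,N,P,P,A,A,P
t10,B,B,W,D,C,D,W,C,N,B,B,N,D,N,N,W,C,C,D,W,L,L,B,N,C,P,P,A,A,P
t11,B,B,W,D,C,D,W,C,N,B,B,N,D,N,N,L,C,C,D,W,L,L,B,N,C,P,P,A,A,P
t12,B,B,W,D,N,D,W,C,N,L,L,D,D,N,N,D,C,C,B,W,L,L,B,C,C,P,P,A,A,P
t13,W,B,D,D,C,C,B,D,N,L,B,L,D,C,N,W,B,D,B,L,L,L,B,C,C,P,P,A,A,P
t14,B,B,W,D,C,D,B,C,N,B,B,N,C,N,N,W,C,N,D,W,L,L,B,W,C,P,P,A,A,P
t15,W,B,D,D,C,B,D,W,N,W,B,L,N,C,N,W,C,D,B,L,L,L,B,N,C,P,P,A,A,P
t16,B,B,W,D,N,D,B,C,N,L,L,D,D,N,N,D,C,C,B,W,L,L,B,C,C,P,P,A,A,P
t17,B,B,W,D,C,D,B,C,N,B,B,N,D,N,N,W,C,C,D,W,L,L,B,N,C,P,P,A,A,P
t18,B,B,W,D,N,D,B,C,N,B,B,L,D,N,N,W,C,C,D,W,C,L,W,C,W,P,P,P,A,P
t19,B,B,W,D,N,D,B,C,N,B,B,N,D,N,N,W,C,C,D,W,C,L,B,C,C,P,P,P,A,P
t20,B,N,W,D,N,D,B,D,N,L,L,W,D,N,N,D,C,C,B,W,L,L,B,C,C,P,P,A,A,P
t21,B,B,W,D,C,D,B,C,B,L,L,L,D,N,N,D,C,C,B,W,D,L,W,C,C,P,P,A,A,P
t22,B,B,W,D,C,N,B,C,N,L,L,D,D,N,C,D,C,C,B,W,L,L,B,C,C,P,P,A,A,P
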