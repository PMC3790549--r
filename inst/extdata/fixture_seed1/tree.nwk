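(((t01:0.25083519474631544,t15:0.25083519474631544):0.60677080235477376,t13:0.8576059971010892):3.4733688319722589,((t22:1.7106504262016031,((((t12:0.05331102364759488,t05:0.05331102364759488):0.41048151235438013,t16:0.46379253600197501):1.0945234577011504,(((t03:0.17794163057188683,t08:0.17794163057188683):0.0027469090725276146,t02:0.18068853964441445):1.1343019613725502,(t04:0.20020669522178025,(t07:0.11394424138408965,t20:0.11394424138408965):0.0862624538376906):1.1147838057951844):0.24332549268616077):0.024445484493782033,t21:1.5827614781969075):0.12788894800469564):1.1844871882953285,((t19:1.3134488515963483,t18:1.3134488515963483):0.50596351301047804,((t06:0.24435303766619398,t14:0.24435303766619398):0.84698693698597083,((t11:0.22237322475518084,t10:0.22237322475518084):0.28371137332353413,(t09:0.37753946515957892,t17:0.37753946515957892):0.12854513291913605):0.58525537657344984):0.7280723899546615):1.0757252498901053):1.4358372145764164);
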