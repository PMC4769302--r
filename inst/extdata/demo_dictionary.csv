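readcode,desc
H331.11,Late onset asthma
8H33.00,Day hospital care
J083300,Ludwig's angina
E273100,Head-banging
13HV400,Seven year itch - marital
G61X.00,Stroke NOS
14A7.00,H/O: sunstroke
E250.00,Alcohol dependence syndrome
136T.00,Alcohol intake above recommended sensible limits
G554000,Ischemic cardiomyopathy
D731.00,Splenomegaly
D737.00,Hypersplenism
7J36000,Splenectomy
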