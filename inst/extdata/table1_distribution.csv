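medication,train_n,train_pct,valid_n,valid_pct,rec_n,rec_pct,train_ok,valid_ok,rec_ok
amisulpride,1552,6.9,674,7.0,2920,30.2,1,1,1
aripiprazole,1353,6.0,614,6.3,3088,31.9,1,1,1
chlorpromazine,231,1.0,103,1.1,119,1.2,1,1,1
clothiapine,149,0.7,47,0.5,2,0.02,1,1,0
flupentixol,381,1.7,158,1.6,55,0.6,1,1,1
haloperidol,1235,5.5,503,5.2,62,0.6,1,1,1
olanzapine,1040,4.6,433,4.5,479,5.0,1,1,1
paliperidone,271,1.2,116,1.2,831,8.6,1,1,1
quetiapine,2274,10.1,1004,10.4,385,4.0,1,1,1
risperidone,6743,29.8,2905,30.0,1069,11.1,1,1,0
sulpiride,6455,18.6,2747,28.4,105,1.1,0,1,1
thioridazine,99,0.4,28,0.3,0,0,1,1,1
trifluoperazine,243,1.1,106,1.1,339,8.5,1,1,0
ziprasidone,238,1.1,101,1.0,0,0,1,1,1
zotepine,337,1.5,137,1.4,222,2.3,1,1,1
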