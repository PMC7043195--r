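medication,pct_recommended,pct_not_recommended,printed_ratio,consistent
amisulpride,7.8,6.6,1.2,1
aripiprazole,7.6,5.8,1.3,1
chlorpromazine,0,1.1,0,1
clothiapine,0,0.5,0,1
flupentixol,0,1.6,0,1
haloperidol,3.2,5.2,0.6,1
olanzapine,3.3,4.5,0.7,1
paliperidone,0.8,1.2,0.7,1
quetiapine,26.2,9.7,2.7,1
risperidone,39.6,28.8,1.4,1
sulpiride,27.6,28.4,1.0,1
thioridazine,0,0,0,1
trifluoperazine,1.8,1.1,1.7,0
ziprasidone,0,0,0,1
zotepine,4.1,1.4,3.0,0
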