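medication,diff_pct,count_without_recommended,printed_contribution_pct
amisulpride,3.8,447,5.9
aripiprazole,5.4,380,7.2
chlorpromazine,28.1,103,10.1
flupentixol,14.2,158,7.8
haloperidol,1.8,501,3.2
olanzapine,10.3,417,15.0
paliperidone,20.3,109,7.7
quetiapine,-4.5,903,-14.2
risperidone,-1.8,2482,-15.6
sulpiride,5.4,2718,51.3
trifluoperazine,16.4,100,5.7
ziprasidone,14.7,101,5.2
zotepine,23.7,128,10.6
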