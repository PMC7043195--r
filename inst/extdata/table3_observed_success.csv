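medication,n_success,n_received,printed_success_pct,consistent
amisulpride,303,674,45.0,1
aripiprazole,277,614,45.1,1
chlorpromazine,38,103,36.9,1
clothiapine,13,47,27.7,1
flupentixol,66,158,41.8,1
haloperidol,204,503,40.6,1
olanzapine,174,433,40.2,1
paliperidone,43,116,37.1,1
quetiapine,434,1004,43.2,1
risperidone,1406,2905,48.4,1
sulpiride,1192,2747,43.4,1
thioridazine,28,28,57.1,0
trifluoperazine,50,106,47.2,1
ziprasidone,44,101,43.6,1
zotepine,49,137,35.8,1
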