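name,code,scope,pt
"Noninfectious myocarditis/pericarditis",20000239,narrow,"Myocarditis"
"Noninfectious myocarditis/pericarditis",20000239,narrow,"Pericarditis"
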