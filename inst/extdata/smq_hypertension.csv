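name,code,scope,pt
"Hypertension",20000147,narrow,"Hypertension"
"Hypertension",20000147,narrow,"Hypertensive crisis"
"Hypertension",20000147,narrow,"Blood pressure increased"
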