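name,code,scope,pt
"Cardiac failure",20000004,narrow,"Cardiac failure"
"Cardiac failure",20000004,narrow,"Cardiac failure congestive"
"Cardiac failure",20000004,narrow,"Cardiogenic shock"
"Cardiac failure",20000004,narrow,"Pulmonary oedema"
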