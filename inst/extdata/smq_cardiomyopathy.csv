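name,code,scope,pt
"Cardiomyopathy",20000150,narrow,"Cardiomyopathy"
"Cardiomyopathy",20000150,narrow,"Congestive cardiomyopathy"
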