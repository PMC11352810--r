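name,code,scope,pt
"Myocardial infarction",20000047,narrow,"Myocardial infarction"
"Myocardial infarction",20000047,narrow,"Acute myocardial infarction"
"Myocardial infarction",20000047,narrow,"Acute coronary syndrome"
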