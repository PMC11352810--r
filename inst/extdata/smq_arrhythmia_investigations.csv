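name,code,scope,pt
"Arrhythmia-related investigations, signs, and symptoms",20000051,narrow,"Heart rate increased"
"Arrhythmia-related investigations, signs, and symptoms",20000051,narrow,"Heart rate irregular"
"Arrhythmia-related investigations, signs, and symptoms",20000051,narrow,"Electrocardiogram abnormal"
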