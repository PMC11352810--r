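name,code,scope,pt
"Torsade de pointes/QT prolongation",20000001,narrow,"Torsade de pointes"
"Torsade de pointes/QT prolongation",20000001,narrow,"Electrocardiogram QT prolonged"
"Torsade de pointes/QT prolongation",20000001,narrow,"Long QT syndrome"
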