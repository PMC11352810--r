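drug_id,type,variant
palbociclib,ingredient,PALBOCICLIB
palbociclib,brand,IBRANCE
ribociclib,ingredient,RIBOCICLIB
ribociclib,brand,KISQALI
abemaciclib,ingredient,ABEMACICLIB
abemaciclib,brand,VERZENIO
abemaciclib,brand,VERZENIOS
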