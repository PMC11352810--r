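name,code,scope,pt
"Cardiac disorders",10007541,narrow,"Atrial fibrillation"
"Cardiac disorders",10007541,narrow,"Arrhythmia"
"Cardiac disorders",10007541,narrow,"Bradycardia"
"Cardiac disorders",10007541,narrow,"Cardiac disorder"
"Cardiac disorders",10007541,narrow,"Cardiac failure"
"Cardiac disorders",10007541,narrow,"Cardiac failure congestive"
"Cardiac disorders",10007541,narrow,"Cardiogenic shock"
"Cardiac disorders",10007541,narrow,"Cardiomyopathy"
"Cardiac disorders",10007541,narrow,"Congestive cardiomyopathy"
"Cardiac disorders",10007541,narrow,"Myocardial infarction"
"Cardiac disorders",10007541,narrow,"Acute myocardial infarction"
"Cardiac disorders",10007541,narrow,"Myocarditis"
"Cardiac disorders",10007541,narrow,"Palpitations"
"Cardiac disorders",10007541,narrow,"Pericarditis"
"Cardiac disorders",10007541,narrow,"Tachycardia"
"Cardiac disorders",10007541,narrow,"Torsade de pointes"
"Cardiac disorders",10007541,narrow,"Ventricular tachycardia"
"Cardiac disorders",10007541,narrow,"Long QT syndrome"
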