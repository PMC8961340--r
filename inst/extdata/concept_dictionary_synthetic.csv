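surface_form,concept_id,icd10_category
palpitations,SYM-R00-01,R00
tachycardia,SYM-R00-02,R00
bradycardia,SYM-R00-03,R00
irregular heartbeat,SYM-R00-04,R00
heart murmur,SYM-R01-01,R01
cardiac murmur,SYM-R01-02,R01
gangrene,SYM-R02-01,R02
elevated blood pressure,SYM-R03-01,R03
low blood pressure,SYM-R03-02,R03
hemoptysis,SYM-R04-01,R04
epistaxis,SYM-R04-02,R04
nosebleed,SYM-R04-03,R04
cough,SYM-R05-01,R05
shortness of breath,SYM-R06-01,R06
dyspnea,SYM-R06-02,R06
wheezing,SYM-R06-03,R06
sob,SYM-R06-04,R06
chest pain,SYM-R07-01,R07
sore throat,SYM-R07-02,R07
chest tightness,SYM-R07-03,R07
rales,SYM-R08-01,R08
stridor,SYM-R08-02,R08
nasal congestion,SYM-R09-01,R09
pleurisy,SYM-R09-02,R09
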