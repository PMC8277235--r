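term	code	label
fever	386661006	Fever
headache	25064002	Headache
rash	271807003	Rash
cough	49727002	Cough
bleeding	131148009	Bleeding
epistaxis	249366005	Epistaxis
abscess	128477000	Abscess
abscesses	128477000	Abscess
abdominal pain	21522001	Abdominal pain
pain	22253000	Pain
diarrhea	62315008	Diarrhea
vomiting	422400008	Vomiting
sore throat	162397003	Sore throat
fatigue	84229001	Fatigue
chills	43724002	Chills
myalgia	68962001	Myalgia
jaundice	18165001	Jaundice
nausea	422587007	Nausea
conjunctivitis	9826008	Conjunctivitis
loss of smell	44169009	Loss of smell
lymphadenopathy	30746006	Lymphadenopathy
dyspnea	267036007	Dyspnea
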