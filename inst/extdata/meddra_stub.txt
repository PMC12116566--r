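Alopecia	10040785	Skin and subcutaneous tissue disorders
Rash	10040785	Skin and subcutaneous tissue disorders
Pruritus	10040785	Skin and subcutaneous tissue disorders
Urticaria	10040785	Skin and subcutaneous tissue disorders
Erythema	10040785	Skin and subcutaneous tissue disorders
Dry skin	10040785	Skin and subcutaneous tissue disorders
Hyperhidrosis	10040785	Skin and subcutaneous tissue disorders
Night sweats	10040785	Skin and subcutaneous tissue disorders
Nail disorder	10040785	Skin and subcutaneous tissue disorders
Onychoclasis	10040785	Skin and subcutaneous tissue disorders
Skin ulcer	10040785	Skin and subcutaneous tissue disorders
Dermatitis bullous	10040785	Skin and subcutaneous tissue disorders
Rash maculo-papular	10040785	Skin and subcutaneous tissue disorders
Angioedema	10040785	Skin and subcutaneous tissue disorders
Rash pruritic	10040785	Skin and subcutaneous tissue disorders
Hair growth abnormal	10040785	Skin and subcutaneous tissue disorders
Anhidrosis	10040785	Skin and subcutaneous tissue disorders
Pseudo cellulitis	10040785	Skin and subcutaneous tissue disorders
Nail toxicity	10040785	Skin and subcutaneous tissue disorders
Nausea	10017947	Gastrointestinal disorders
Vomiting	10017947	Gastrointestinal disorders
Diarrhoea	10017947	Gastrointestinal disorders
Headache	10029205	Nervous system disorders
Dizziness	10029205	Nervous system disorders
Fatigue	10018065	General disorders and administration site conditions
Arthralgia	10028395	Musculoskeletal and connective tissue disorders
Dyspnoea	10038738	Respiratory, thoracic and mediastinal disorders
Anaemia	10005329	Blood and lymphatic system disorders
Insomnia	10037175	Psychiatric disorders
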