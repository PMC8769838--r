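id	label
poisoning	Poisoning/intoxication
circulatory	Circulatory disease
gastrointestinal	Gastrointestinal disease
nervous	Nervous system disease
eye	Eye disease
general	Other/general disease
hepatobiliary	Hepatobiliary disease
musculoskeletal	Musculoskeletal disease
oral	Oral disease
ent	Ear/nose/throat disease
pediatric	Pediatric disease
reproductive	Reproductive system disease
respiratory	Respiratory disease
skin	Skin disease
urinary	Urinary disease
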