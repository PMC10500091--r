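format-version: 1.2
ontology: hp

[Term]
id: HP:0000001
name: All

[Term]
id: HP:0000118
name: Phenotypic abnormality
is_a: HP:0000001 ! All

[Term]
id: HP:0000707
name: Abnormality of the nervous system
alt_id: HP:0001333
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0012638
name: Abnormal nervous system physiology
is_a: HP:0000707 ! Abnormality of the nervous system

[Term]
id: HP:0012639
name: Abnormal nervous system morphology
is_a: HP:0000707 ! Abnormality of the nervous system

[Term]
id: HP:0001250
name: Seizure
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0001298
name: Encephalopathy
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0200134
name: Epileptic encephalopathy
is_a: HP:0001250 ! Seizure
is_a: HP:0001298 ! Encephalopathy

[Term]
id: HP:0002133
name: Status epilepticus
is_a: HP:0001250 ! Seizure

[Term]
id: HP:0007359
name: Focal-onset seizure
is_a: HP:0001250 ! Seizure

[Term]
id: HP:0002345
name: Action tremor
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0010520
name: obsolete Bilateral tonic-clonic seizures
is_obsolete: true
replaced_by: HP:0002133
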