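format-version: 1.2
data-version: toy/2024-01-01
ontology: toy-phenotype-synthetic
remark: Entirely synthetic miniature phenotype ontology used as the test
remark: substrate for this package. Concept IDs, labels and hierarchy are
remark: invented; the shape (labels + exact synonyms, alt_id, is_a) mirrors
remark: what a real phenotype ontology provides.

[Term]
id: TOY:0000001
name: Phenotypic abnormality

[Term]
id: TOY:0000002
name: Cataract
synonym: "Lens opacity" EXACT []
is_a: TOY:0000001 ! Phenotypic abnormality

[Term]
id: TOY:0000003
name: Hip dysplasia
synonym: "Dysplastic hip joints" EXACT []
is_a: TOY:0000012 ! Abnormal skeletal morphology

[Term]
id: TOY:0000004
name: Abnormal urinary acylglycine profile
is_a: TOY:0000001 ! Phenotypic abnormality

[Term]
id: TOY:0000005
name: Pseudohypoaldosteronism
is_a: TOY:0000001 ! Phenotypic abnormality

[Term]
id: TOY:0000006
name: Shortening of the finger phalanges
synonym: "Short phalanx of finger" EXACT []
is_a: TOY:0000012 ! Abnormal skeletal morphology

[Term]
id: TOY:0000007
name: Abnormal muscle tone
is_a: TOY:0000001 ! Phenotypic abnormality

[Term]
id: TOY:0000008
name: Seizure
alt_id: TOY:0000999
is_a: TOY:0000001 ! Phenotypic abnormality

[Term]
id: TOY:0000009
name: Scoliosis
is_a: TOY:0000012 ! Abnormal skeletal morphology

[Term]
id: TOY:0000010
name: Global developmental delay
is_a: TOY:0000001 ! Phenotypic abnormality

[Term]
id: TOY:0000011
name: Micrognathia
is_a: TOY:0000012 ! Abnormal skeletal morphology

[Term]
id: TOY:0000012
name: Abnormal skeletal morphology
is_a: TOY:0000001 ! Phenotypic abnormality

[Term]
id: TOY:0000013
name: Elevated urinary glutarylcarnitine level
is_a: TOY:0000001 ! Phenotypic abnormality

[Term]
id: TOY:0000014
name: Hypertelorism
synonym: "Widely spaced eyes" EXACT []
is_a: TOY:0000001 ! Phenotypic abnormality

[Term]
id: TOY:0000050
name: Clinical modifier

[Term]
id: TOY:0000051
name: Obsolete dysplastic marker
is_obsolete: true
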