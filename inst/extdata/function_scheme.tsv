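category	subcategory
General	protein interaction
General	small molecule binding
General	ion binding
General	ligand binding
General	structural protein
Information	translation
Information	transcription
Information	DNA replication/repair
Information	RNA processing
Information	nuclear structure
Information	chromatin structure
Metabolism	nucleotide m/tr
Metabolism	coenzyme m/tr
Metabolism	amino acids m/tr
Metabolism	carbohydrate m/tr
Metabolism	polysaccharide m/tr
Metabolism	lipid m/tr
Metabolism	nitrogen m/tr
Metabolism	electron transfer
Metabolism	transferases
Metabolism	other enzymes
Metabolism	redox
Metabolism	secondary metabolism
Metabolism	energy
Metabolism	storage
Metabolism	photosynthesis
Metabolism	cell envelope m/tr
Intra-cellular processes	protein modification
Intra-cellular processes	transport
Intra-cellular processes	proteases
Intra-cellular processes	ion m/tr
Intra-cellular processes	cell cycle/apoptosis
Intra-cellular processes	phospholipid m/tr
Intra-cellular processes	cell motility
Intra-cellular processes	trafficking/secretion
Extra-cellular processes	cell adhesion
Extra-cellular processes	toxins/defense
Extra-cellular processes	immune response
Extra-cellular processes	extracellular structure
Regulation	kinases/phosphatases
Regulation	DNA-binding
Regulation	RNA binding
Regulation	receptor activity
Regulation	signal transduction
Regulation	other regulatory function
Other	unknown function
Other	viral proteins
Other	general function
Other	not annotated
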