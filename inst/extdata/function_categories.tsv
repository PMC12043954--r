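label	category
terminase large subunit	packaging
terminase small subunit	packaging
portal protein	packaging
major capsid protein	structural
minor capsid protein	structural
capsid	structural
baseplate protein	structural
tail fiber protein	structural
phage tail tube protein	structural
tail sheath protein	structural
head-tail connector protein	structural
DNA polymerase	replication
RNA polymerase	replication
DNA primase	replication
DNA helicase	replication
ribonucleotide reductase	nucleotide_metabolism
dCTP deaminase	nucleotide_metabolism
dTMP kinase	nucleotide_metabolism
dUTP diphosphatase	nucleotide_metabolism
nucleotide kinase	nucleotide_metabolism
integrase	lysogeny
excisionase	lysogeny
repressor protein	lysogeny
antirepressor	lysogeny
helix-turn-helix domain	regulation
transcriptional regulator	regulation
lysin	lysis
holin	lysis
endolysin	lysis
essential recombination function protein	recombination
recombinase	recombination
exonuclease	recombination
PhoH	auxiliary
pyruvate formate-lyase activating enzyme	auxiliary
cobaltochelatase subunit CobS	auxiliary
cobaltochelatase subunit CobT	auxiliary
phosphoribosylformylglycinamidine cyclo-ligase	auxiliary
phosphoribosylamine-glycine ligase	auxiliary
hypothetical protein	unknown
uncharacterized protein	unknown
domain of unknown function	unknown
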