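# Annotation relation vocabulary: slot <TAB> predicate IRI.
# SemSim-style relation names; swap this file to read another dialect.
property	http://bhi.washington.edu/SemSim#hasPhysicalProperty
chemical	http://bhi.washington.edu/SemSim#hasPhysicalEntity
source	http://bhi.washington.edu/SemSim#hasSourceParticipant
sink	http://bhi.washington.edu/SemSim#hasSinkParticipant
located_in	http://bhi.washington.edu/SemSim#isLocatedIn
mediator	http://bhi.washington.edu/SemSim#hasMediatorParticipant
refers_to	http://bhi.washington.edu/SemSim#refersTo
part_of	http://bhi.washington.edu/SemSim#partOf
species	http://bhi.washington.edu/SemSim#hasSpecies
gene	http://bhi.washington.edu/SemSim#hasGene
model_title	http://purl.org/dc/terms/title
label	http://www.w3.org/2000/01/rdf-schema#label
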