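# Seed term-mapping dictionary: key <TAB> prefix:id <TAB> uri [<TAB> label]
# Covers the epithelial-transport vocabulary used by the synthetic fixture
# corpus. Term IRIs live in the reserved example.org namespace so they can
# never be mistaken for real ontology identifiers.
flux	OPB:OPB_00593	https://example.org/onto/OPB_00593	flux
concentration	OPB:OPB_00340	https://example.org/onto/OPB_00340	concentration
sodium	CHEBI:CHEBI_29101	https://example.org/onto/CHEBI_29101	sodium
hydrogen	CHEBI:CHEBI_15378	https://example.org/onto/CHEBI_15378	hydrogen
glucose	CHEBI:CHEBI_17234	https://example.org/onto/CHEBI_17234	glucose
potassium	CHEBI:CHEBI_29103	https://example.org/onto/CHEBI_29103	potassium
apical	FMA:FMA_67697	https://example.org/onto/FMA_67697	apical plasma membrane
basolateral	FMA:FMA_84669	https://example.org/onto/FMA_84669	basolateral plasma membrane
membrane	FMA:FMA_67697	https://example.org/onto/FMA_67697	apical plasma membrane
membrane	FMA:FMA_84669	https://example.org/onto/FMA_84669	basolateral plasma membrane
cytosol	FMA:FMA_66836	https://example.org/onto/FMA_66836	cytosol
proximal tubule	FMA:FMA_17693	https://example.org/onto/FMA_17693	proximal tubule
lumen	FMA:FMA_74268	https://example.org/onto/FMA_74268	tubule lumen
interstitial	FMA:FMA_9673	https://example.org/onto/FMA_9673	interstitial fluid
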