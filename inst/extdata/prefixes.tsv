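# Prefix registry: prefix <TAB> IRI stem. Longest matching stem wins;
# unmatched IRIs classify as OTHER. example.org stems are reserved for the
# synthetic fixture corpus.
OPB	http://bhi.washington.edu/OPB#
OPB	http://identifiers.org/opb/
FMA	http://purl.org/sig/ont/fma/
FMA	http://identifiers.org/fma/
CHEBI	http://purl.obolibrary.org/obo/CHEBI_
CHEBI	https://identifiers.org/CHEBI:
PR	http://purl.obolibrary.org/obo/PR_
PR	https://identifiers.org/pr/
GO	http://purl.obolibrary.org/obo/GO_
UNIPROT	http://identifiers.org/uniprot/
UNIPROT	https://www.uniprot.org/uniprot/
OPB	https://example.org/onto/OPB_
FMA	https://example.org/onto/FMA_
CHEBI	https://example.org/onto/CHEBI_
PR	https://example.org/onto/PR_
UNIPROT	https://example.org/protein/
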