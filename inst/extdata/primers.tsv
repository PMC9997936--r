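name	direction	sequence	pair_label
ITS5	forward	GGAAGTAAAAGTCGTAACAAGG	universal
ITS4	reverse	TCCTCCGCTTATTGATATGC	universal
Hsprp1	forward	ATTATCGAGTCACCACTCCCAAACCCCC	GC-biased Genotype #1
Hsprp2	reverse	ATTTGCTTGCTTCTTGACTGAGAGATGCC	GC-biased Genotype #1
Hsprp3	reverse	CGAGGTTCTCAGCGAGCTACT	GC-biased Genotype #1
HsATp1	forward	AAGGTCTCCGTTAGTAAACT	AT-biased genotypes
HsATp2	reverse	GGGGCTCGAGGGTTAAGATA	AT-biased genotypes
HsATp3	reverse	GGGGCTTAAGGGTTAAGGTA	AT-biased genotypes
Prp2	forward	ATTACACTTTGTTGCTTTGGCA	G. pannorum / P. roseus
Prp5	reverse	GCTGGCGAGCACACGACCGGACCT	G. pannorum / P. roseus
Pcp3	forward	GAGGGCCCTCTGGGTCCAACC	P. chrysogenum
Pcp7	reverse	CCCCATACGCTCGAGGACC	P. chrysogenum
Php4	forward	GTATCTTCTGAATCCGCCGCAAGGC	S. hepiali
Php6	reverse	AACGTTCAGAAGTCGGGGGTTTTAC	S. hepiali
Tsp1	forward	GACCGCCCCGGCGCCCTCG	T. sinensis
Tsp3	reverse	TGACCGTCTCCGCGCT	T. sinensis
M13F	forward	TGTAAAACGACGGCGT	vector
M13R	reverse	CAGGAAACAGCTATCC	vector
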