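forward	reverse	label	target
ITS5	ITS4	ITS5/ITS4	universal
Hsprp1	Hsprp2	Hsprp1/Hsprp2	GC-biased Genotype #1
Hsprp1	Hsprp3	Hsprp1/Hsprp3	GC-biased Genotype #1
HsATp1	ITS4	HsATp1/ITS4	AT-biased genotypes
HsATp1	HsATp2	HsATp1/HsATp2	AT-biased genotypes (#5, #15, #17)
HsATp1	HsATp3	HsATp1/HsATp3	AT-biased genotypes (#4, #16)
Prp2	Prp5	Prp2/Prp5	G. pannorum / P. roseus
Pcp3	Pcp7	Pcp3/Pcp7	P. chrysogenum
Php4	Php6	Php4/Php6	S. hepiali
Tsp1	Tsp3	Tsp1/Tsp3	T. sinensis
M13F	M13R	M13F/M13R	vector
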