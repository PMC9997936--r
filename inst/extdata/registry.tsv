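accession	genotype_id	class	cluster	note
AB067721	#1	GC-biased	GC	Hirsutella sinensis, Genotype #1 representative
KT339196	#1	GC-biased	GC	Genotype #1, current-study representative
MG770309	#2	GC-biased	GC	
HM595984	#3	GC-biased	GC	
AB067744	#4	AT-biased	B	
AB067740	#5	AT-biased	A	
EU555436	#6	AT-biased	A	partial-length record
AJ488254	#7	GC-biased	GC	
GU246286	#8	GC-biased	GC	
GU246288	#9	GC-biased	GC	
GU246287	#10	GC-biased	GC	
JQ695935	#11	GC-biased	GC	
GU246296	#12	GC-biased	GC	
KT339190	#13	GC-biased	GC	recombinant, parents #1 and AB067719-type
KT339178	#14	GC-biased	GC	recombinant, parents #1 and AB067719-type
KT232017	#15	AT-biased	B	
KT232019	#16	AT-biased	A	
KT232010	#17	AT-biased	A	
AB067719	AB067719-type	outgroup	none	Group-E fungus, outgroup
KT339197	AB067719-type	outgroup	none	Group-E fungus, current-study representative
EF555097	S.hepiali	species-control	none	Samsoniella hepiali
AY608922	P.roseus	species-control	none	Pseudogymnoascus roseus
JF320819	G.pannorum	species-control	none	Geomyces pannorum
DQ189229	G.pannorum	species-control	none	Geomyces pannorum
DQ336710	P.chrysogenum	species-control	none	Penicillium chrysogenum
DQ097715	T.sinensis	species-control	none	Tolypocladium sinensis
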