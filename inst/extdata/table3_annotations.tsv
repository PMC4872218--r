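protein_id	accession	tm_domains	protein_function
alpha-tubulin 4	gi|37529490	0	Cytoskeleton, GTPase activity, guidance of cellulose deposition
beta-tubulin 3	gi|223453022	0	Cytoskeleton, GTPase activity, protein binding, guidance of cellulose deposition
beta-tubulin 7	gi|37529498	0	Cytoskeleton, GTPase activity, protein binding, guidance of cellulose deposition
endo-1,4-beta-glucanase (KOR)	gi|32454474	1	cellulase activity, cellulose biosynthesis
sucrose synthase 1	gi|258489633	0	UDP-glycosyltransferase activity, cellulose biosynthesis
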