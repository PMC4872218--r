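protein_id	association	printed_group	accession	tm_domains	protein_function
phenylcoumaran benzylic ether reductase-like protein	CESA-associated	I	gi|124488476	0	isoflavone reductase
vacuolar H+-ATPase catalytic subunit	CESA-associated	I	gi|167313	0	cytoskeleton, ATP binding, hydrolase activity
glyceraldehyde-3-phosphate dehydrogenase C subunit	CESA-associated	II	gi|211906518	0	NAD binding, NADP binding, oxidoreductase activity
fasciclin-like arabinogalactan protein	CESA-associated	II	gi|606942	1	cell wall biogenesis, acetyl-CoA metabolic process
UDP-glucuronic acid decarboxylase 2	CESA-associated	II	gi|213950353	1	UDP-xylose metabolic, UDP-glucuronate decarboxylase activity
tonoplast intrinsic protein	CESA-associated	II	gi|227434194	6	water channel, facilitate the transport of urea and hydrogen peroxide
ubiquitin extension protein	CALS-associated	I	gi|73761683	0	structural constituent of ribosome, ubiquitin-dependent protein catabolic process
3-ketoacyl-CoA reductase 1	CALS-associated	I	gi|62956018	1	acetoacetyl-CoA reductase, ketoreductase, oxidoreductase
plasma membrane H+-ATPase, partial	CALS-associated	II	gi|2911803	9	ATPase activity, cation transport
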