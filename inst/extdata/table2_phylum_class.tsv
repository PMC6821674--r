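level	row	gel_based.TAX	gel_based.NAM	gel_based.AM	gel_based.Comb	gel_free.TAX	gel_free.NAM	gel_free.AM	gel_free.Comb
phylum	Proteobacteria	87.2	92.7	95.2	89.8	87.6	92.9	91.5	90.0
phylum	Cyanobacteria	6.3	2.9	2.0	4.0	2.6	4.8	1.6	2.0
phylum	Bacteroidetes	4.9	4.2	2.4	5.0	7.6	1.4	6.1	5.8
phylum	Other	1.6	0.2	0.4	1.2	2.2	0.9	0.8	2.2
class	Alphaproteobacteria	73.7	81.6	79.9	74.3	69.7	68.4	68.4	67.5
class	Gammaproteobacteria	12.9	11.5	14.8	14.4	18.0	25.7	24.4	23.5
class	Flavobacteriia	6.5	3.7	2.2	3.9	6.3	3.5	4.9	4.8
class	Unclassified Cyanobacteria	3.9	2.7	1.8	5.3	2.5	1.4	1.2	2.1
class	Other	3.0	0.5	1.2	2.1	3.6	1.0	1.0	2.2
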