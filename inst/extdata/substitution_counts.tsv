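# Published pairwise substitution counts for five Chimonanthus species
# against C. praecox, by unordered base-pair category (concatenated
# protein-coding genes). Input data for the Ts/Tv consistency computation.
species	AC	CT	AG	AT	CG	GT
zhejiangensis	57	106	101	16	12	58
salicifolius	60	110	103	10	13	58
nitens_b	57	109	103	15	12	61
grammatus	55	112	102	13	15	55
campanulatus	48	72	75	12	13	49
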