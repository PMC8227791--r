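file	md5
table1_edr.tsv	8d1688e8545be5295f48cf0860006177
table1_ked.tsv	cfc444d413c22a296249f2c80769fb2a
table2_occurrences.tsv	029c9c8a10d8281711b6a719e03025aa
ad_gene_list.txt	29c0fbc29f040357ab1b4f8ee08b0b2d
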