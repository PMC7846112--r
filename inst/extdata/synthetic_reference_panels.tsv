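name	n_individuals	alt_allele_count
gnomAD	141456	2
G100K	139707	0
NIHR_RD	13037	0
H3Africa	50000	0
GenomeAsia100K	1739	0
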