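# Assembly-level constants of the census.
name	value
genome_bp	273093681
ltr_total_bp	3197007
n_insertions_total	1045
n_families	73
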