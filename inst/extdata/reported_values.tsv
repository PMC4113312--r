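quantity	op	input_a	input_b	input_c	reported
mean_contig_length_bp	divide_int	823673596	94267	NA	8738
kmer_genome_coverage_pct	pct_1dp	877777613	911413085	NA	96.3
est_contigs_mapped_pct	pct_1dp	11263	11662	NA	96.6
est_primer_polymorphic_pct	pct_int	187	776	NA	24
polymorphic_markers_total	sum	187	378	NA	565
primer_pairs_screened_total	sum	776	835	NA	1611
markers_mapped	sum_minus	565	27	12	526
female_male_recombination_ratio	ratio_2dp	1245.4	1166.0	NA	1.07
half_sib_family_progeny	sum	48	44	NA	92
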