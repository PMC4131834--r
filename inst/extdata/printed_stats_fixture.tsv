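name	value
kn_aligned_bp	278750000
k93_aligned_bp	259000000
reference_genome_bp	373250000
printed_kn_snp_total	2787250
printed_kn_indel_total	7393
printed_k93_snp_total	2216251
printed_k93_indel_total	3780
printed_kn_snp_frequency_pct	1.00
printed_k93_snp_frequency_pct	0.86
printed_kn_mean_indel_bp	1999
printed_k93_mean_indel_bp	735
printed_unmapped_mean_len	2749
printed_assembly_total_mb	330.55
printed_genome_coverage_pct	88.6
printed_anchored_fraction_pct	87.7
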