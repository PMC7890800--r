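# somafilt filter configuration (filter_name<TAB>threshold)
# preset: default
min_depth_tumor	10.00
min_depth_normal	10.00
min_alt_count_tumor	3.00
min_vaf_tumor	0.05
max_vaf_normal	0.03
max_alt_count_normal	1.00
min_median_bq_alt_tumor	30.00
min_median_mq_alt_tumor	40.00
strand_minor_frac_alt_tumor	0.05
min_median_dist_readend_alt_tumor	10.00
min_mad_pos_alt_tumor	3.00
max_softclip_frac_alt_tumor	0.30
max_excess_nm_alt_tumor	2.00
max_mq0_frac_tumor	0.10
max_near_indel_frac_tumor	0.30
max_improper_pair_frac_alt_tumor	0.50
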