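category	n_peptides	n_proteins
total_detected	7960	519
immune_system	3695	142
muscle	800	41
quantitative_higher_in_long	731	128
quantitative_lower_in_long	61	32
missingness_higher_in_long	25	21
missingness_lower_in_long	69	56
longevity_associated_immune	437	58
longevity_associated_muscle	12	2
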