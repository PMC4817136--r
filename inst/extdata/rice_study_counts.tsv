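quantity	value
ism_markers	84634
ism_genes	20533
ilp_markers	16510
ilp_genes	9816
intronic_indels	29946
flp_bin_1_4	12260
n_tested_total	5745
ism_tested	3217
ilp_tested	2528
n_amplified_total	4629
ism_amplified	2479
ilp_amplified	2150
ism_polymorphic	1329
ilp_polymorphic	1723
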