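# Published summary values for the IRSC apple 8K SNP array v1 design.
# Each row is recomputed by consistency_checks(): inputs are the published
# counts, expected is the published derived value at the stated rounding.
check_id	op	inputs	expected
lg1_avg_snp_spacing_bp	floor_div	36084648;102825	350
lg2_avg_snp_spacing_bp	floor_div	40172783;144715	277
lg3_avg_snp_spacing_bp	floor_div	39907579;134595	296
lg4_avg_snp_spacing_bp	floor_div	25411901;91212	278
lg5_avg_snp_spacing_bp	floor_div	37603833;134672	279
lg6_avg_snp_spacing_bp	floor_div	30670413;97014	316
lg7_avg_snp_spacing_bp	floor_div	31181013;117652	265
lg8_avg_snp_spacing_bp	floor_div	35800717;114173	313
lg9_avg_snp_spacing_bp	floor_div	37514065;146472	256
lg10_avg_snp_spacing_bp	floor_div	38388612;146102	262
lg11_avg_snp_spacing_bp	floor_div	40097013;146718	273
lg12_avg_snp_spacing_bp	floor_div	36276268;121739	297
lg13_avg_snp_spacing_bp	floor_div	39686055;158912	249
lg14_avg_snp_spacing_bp	floor_div	34156235;114259	298
lg15_avg_snp_spacing_bp	floor_div	55775419;159368	349
lg16_avg_snp_spacing_bp	floor_div	23462870;85530	274
lg17_avg_snp_spacing_bp	floor_div	27122502;97162	279
genome_avg_snp_spacing_bp	floor_div	609311926;2113120	288
exonic_snp_pct	pct_1dp	611599;2113120	28.9
goldengate_polymorphic_pct	pct_1dp	73;144	50.7
goldengate_failed_pct	pct_1dp	46;144	31.9
array_polymorphic_pct	pct_1dp	5554;7692	72.2
polymorphic_cluster_pct	pct_1dp	1270;1355	93.7
snps_per_cluster	ratio_1dp	7867;1355	5.8
focal_point_total	sum	712;128;2	842
array_total_snps	sum	693;6028;1072;74	7867
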