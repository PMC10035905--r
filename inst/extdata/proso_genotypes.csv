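accession,potential_grains_per_head,potential_grain_growth_rate,tt_emerg_to_endjuv,photoperiod_sensitivity,tt_flower_to_maturity,tt_flagleaf_to_flower,tt_flower_to_startgrainfill,tt_maturity_to_ripe
L_1,2940,0.61,348.5,112.4,440,85,83,1
L_11,2645,0.61,322,112.4,466,90.5,80,1
L_12,3140,0.61,345,112.4,437,94,86,1
L_14,2795,0.61,331,112.4,450,87,91,1
L_25,3210,0.61,339,112.4,457,70,95,1
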