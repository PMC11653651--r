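contrast	mirna_id	log2fc
DD_vs_HC	bta-miR-6119-3p	-1.5
DD_vs_HC	bta-miR-2408	-1.46
DD_vs_HC	bta-miR-340	-1.01
FR_vs_HC	bta-miR-6119-3p	-1.29
FR_vs_HC	bta-miR-125a	-1.01
FR_vs_HC	bta-miR-200c	1.14
FR_vs_HC	bta-miR-30a-5p	1.17
FR_vs_HC	bta-miR-10225a	1.31
FR_vs_HC	bta-miR-206	1.81
FR_vs_HC	bta-miR-133a	2.45
FRDD_vs_HC	bta-miR-6119-3p	-1.75
FRDD_vs_HC	bta-miR-1434-3p	-1.58
FRDD_vs_HC	bta-miR-211	-1.23
FRDD_vs_HC	bta-miR-1246	-1.09
FRDD_vs_HC	bta-miR-125a	-1.09
FRDD_vs_HC	bta-miR-484	-1.08
FRDD_vs_HC	bta-miR-92b	-1.07
FRDD_vs_HC	bta-miR-1306	-1.03
FRDD_vs_HC	bta-miR-2378	1.03
FRDD_vs_HC	bta-miR-338	1.04
FRDD_vs_HC	bta-miR-497	1.12
FRDD_vs_HC	bta-miR-210	1.17
FRDD_vs_HC	bta-miR-345-5p	1.47
FRDD_vs_HC	bta-miR-21-3p	1.71
TTN_vs_HC	bta-miR-6119-3p	-1.36
TTN_vs_HC	bta-miR-2408	-1.22
TTN_vs_HC	bta-miR-340	-1.12
TTN_vs_HC	bta-miR-1	2.67
TTN_vs_HC	bta-miR-206	2.94
TTN_vs_HC	bta-miR-133a	4.32
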