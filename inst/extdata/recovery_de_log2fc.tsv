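phenotype	week	mirna_id	log2fc
DD	W0	bta-miR-1	3.89
FRDD	W0	bta-miR-2903	-2.23
FRDD	W0	bta-miR-874	-1.05
FRDD	W0	bta-miR-33b	1.58
FRDD	W1	bta-miR-339a	-6.37
TTN	W1	bta-miR-1246	7.68
TTN	W2	bta-miR-9-5p	1.78
TTN	W2	bta-miR-296-3p	-1.17
TTN	W2	bta-miR-6523a	-1.31
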