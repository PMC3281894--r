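model	BT	EYR	FH	GST	SFW	SPP	STP	WB	WPH	YTH
TREE_1_2	4	4	1	1	4	1	3	1	3	1
TREE_1_10	2	2	4	4	2	4	3	3	3	3
HAB_1_2	4	4	1	1	4	1	NA	1	3	1
HAB_1_10	2	2	4	4	2	4	NA	3	3	3
EO_5000	1	1	6	4	1	NA	NA	3	3	3
PANMIXIA	7	7	3	7	7	6	1	6	2	6
IBD	6	6	7	3	6	3	1	7	1	7
IBD_STRENGTH	strong	strong	none	weak	strong	weak	weak	weak	weak	none
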