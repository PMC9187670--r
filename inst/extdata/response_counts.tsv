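# Central radiology review: overall response category counts per follow-up
# timepoint for all enrolled subjects. Columns are study weeks 6, 12, 20, 28.
# Counts in every column sum to the number enrolled.
# n_enrolled=52
# n_assessable=50
# pr_any_time=5
category	wk6	wk12	wk20	wk28
CR	0	0	0	0
PR	0	2	3	3
SD	37	19	13	8
PD	9	6	2	2
progression_before_scan	1	16	25	29
withdrawn_before_scan	3	6	7	8
missing	2	3	2	2
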