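n_calls	n_truth	tp	fp	fn	recall	precision	f1	gt_concordance	median_shift
40	40	40	0	0	1	1	1	0.925	0
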