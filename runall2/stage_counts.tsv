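stage	n
contig_signatures	56
intrahap_clusters	56
paired_calls	40
read_signatures	665
after_support_filter	40
after_del_depth_filter	40
after_dedupe	40
complex_candidates	0
complex_final	0
small_indel_candidates	0
small_indels_final	0
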