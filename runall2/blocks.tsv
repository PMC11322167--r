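block_id	chrom	start	end
1	chr1	0	250000
2	chr1	250000	5e+05
3	chr1	5e+05	750000
4	chr1	750000	1e+06
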