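library	polymerase_reads	polymerase_reads_postfilter	total_subread_bases	subread_count	subreads_n50
1-2K	150292	107731	3099865656	1848503	1696
2-3K	150292	115408	3208845527	1096181	3050
3-6K	150292	108719	3050228963	902878	3835
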