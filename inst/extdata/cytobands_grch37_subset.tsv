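# Approximate GRCh37 cytoband spans (0-based half-open) covering the
# packaged syndrome regions only; not a full cytoband table.
chrom	start	end	band
chr7	67500000	72200000	q11.22
chr7	72200000	77500000	q11.23
chr22	17900000	22200000	q11.21
chr15	22700000	28400000	q11q13
chr5	0	12500000	p15
chr1	0	12500000	p36
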