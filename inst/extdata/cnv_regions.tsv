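label	chrom	start	end	direction
del1p_1p12	chr1	117600000	120400000	loss
del1p_1p22_1	chr1	92000000	94300000	loss
del1p_1p32_3	chr1	50200000	55600000	loss
gain1q21	chr1	143200000	147500000	gain
del17p	chr17	6500000	10800000	loss
del13q	chr13	46200000	50600000	loss
del14q	chr14	89800000	106800000	loss
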