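# Homoeolog-pair bias counts reported for a resynthesized Brassica napus
# allotetraploid (16,915 expressed pairs): progeny bias states and
# parental-to-progeny transitions.
table	stratum	count
progeny	A_biased	3223
progeny	C_biased	2947
progeny	no_bias	10745
transition	maintained	10705
transition	novel	2999
transition	reverted	3211
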