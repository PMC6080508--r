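# Expression-level-dominance group counts reported for a resynthesized
# Brassica napus allotetraploid over 16,915 expressed homoeolog pairs.
stratum	count
no_change	7863
eld	6699
additivity	833
transgressive	1520
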