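# Homoeolog-change cross-tabulation of the 6,699 ELD pairs of a
# resynthesized Brassica napus allotetraploid. category "all" sums over the
# four ELD categories (the published sums determine every cell); category
# "IV" lists the published cells of the A-dominant higher-parent class.
category	change_A	change_C	n
all	up	unchanged	169
all	up	down	58
all	up	up	0
all	down	unchanged	1759
all	down	down	569
all	down	up	232
all	unchanged	up	295
all	unchanged	down	601
all	unchanged	unchanged	3016
IV	down	down	208
IV	down	unchanged	1220
IV	down	up	232
IV	unchanged	up	293
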