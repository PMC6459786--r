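class	artifact	physiological	pathological
artifact	23253	1241	895
physiological	3073	38647	2539
pathological	20	1549	4530
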