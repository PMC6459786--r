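class	line_noise_60	artifact	physiological	pathological
line_noise_60	19949	171	487	19
artifact	44	23084	183	47
physiological	87	531	39625	475
pathological	0	29	454	5128
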