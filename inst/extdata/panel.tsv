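name	formula	hmdb_id	rt_pos	rt_neg	adducts	max_isotope
Tetradecenoylcarnitine	C21H39NO4	HMDB0002014	13.37	NA	M+H;M+Na	1
Dodecanoylcarnitine	C19H37NO4	HMDB0002250	12.24	NA	M+H;M+Na	1
Tetradecadienoylcarnitine	C21H37NO4	HMDB0013331	12.82	NA	M+H;M+Na	1
Tetradecanoylcarnitine	C21H41NO4	HMDB0005066	13.82	NA	M+H;M+Na	1
Hexadecenoylcarnitine	C23H43NO4	HMDB0013207	14.08	NA	M+H;M+Na	1
Palmitoylcarnitine	C23H45NO4	HMDB0000222	14.52	NA	M+H;M+Na	1
Linoleoylcarnitine	C25H45NO4	HMDB0006469	14.32	NA	M+H;M+Na	1
Oleoylcarnitine	C25H47NO4	HMDB0013338	14.69	NA	M+H;M+Na	1
Stearoylcarnitine	C25H49NO4	HMDB0000848	15.08	NA	M+H;M+Na	1
Dihydrouracil	C4H6N2O2	HMDB0000076	1.8	NA	M+H;M+Na;M-H;M+Cl	1
Ornithine	C5H12N2O2	HMDB0000214	1	NA	M+H;M+Na;M-H;M+Cl	1
Xanthine	C5H4N4O2	HMDB0000292	2.6	2.6	M+H;M+Na;M-H;M+Cl	1
Pimelic acid	C7H12O4	HMDB0000857	5.4	5.4	M+H;M+Na;M-H;M+Cl	1
L-Phenylalanine	C9H11NO2	HMDB0000159	4.9	4.9	M+H;M+Na;M-H;M+Cl	1
L-Tyrosine	C9H11NO3	HMDB0000158	3.8	3.8	M+H;M+Na;M-H;M+Cl	1
N-Acetylmannosamine	C8H15NO6	HMDB0001129	2.1	2.1	M+H;M+Na;M-H;M+Cl	1
gamma-Glutamylphenylalanine	C14H18N2O5	HMDB0000594	5.8	5.8	M+H;M+Na;M-H;M+Cl	1
Mesaconic acid	C5H6O4	HMDB0000749	NA	4.2	M+H;M+Na;M-H;M+Cl	1
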