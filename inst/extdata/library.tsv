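id	name	formula
HMDB0002014	Tetradecenoylcarnitine	C21H39NO4
HMDB0002250	Dodecanoylcarnitine	C19H37NO4
HMDB0013331	Tetradecadienoylcarnitine	C21H37NO4
HMDB0005066	Tetradecanoylcarnitine	C21H41NO4
HMDB0013207	Hexadecenoylcarnitine	C23H43NO4
HMDB0000222	Palmitoylcarnitine	C23H45NO4
HMDB0006469	Linoleoylcarnitine	C25H45NO4
HMDB0013338	Oleoylcarnitine	C25H47NO4
HMDB0000848	Stearoylcarnitine	C25H49NO4
HMDB0000076	Dihydrouracil	C4H6N2O2
HMDB0000214	Ornithine	C5H12N2O2
HMDB0000292	Xanthine	C5H4N4O2
HMDB0000857	Pimelic acid	C7H12O4
HMDB0000159	L-Phenylalanine	C9H11NO2
HMDB0000158	L-Tyrosine	C9H11NO3
HMDB0001129	N-Acetylmannosamine	C8H15NO6
HMDB0000594	gamma-Glutamylphenylalanine	C14H18N2O5
HMDB0000749	Mesaconic acid	C5H6O4
HMDB0000562	Creatinine	C4H7N3O
HMDB0000064	Creatine	C4H9N3O2
HMDB0000062	L-Carnitine	C7H15NO3
HMDB0000201	Acetylcarnitine	C9H17NO4
HMDB0000122	D-Glucose	C6H12O6
HMDB0000289	Uric acid	C5H4N4O3
HMDB0000714	Hippuric acid	C9H9NO3
HMDB0000929	L-Tryptophan	C11H12N2O2
HMDB0000687	L-Leucine	C6H13NO2
HMDB0000094	Citric acid	C6H8O7
HMDB0000251	Taurine	C2H7NO3S
HMDB0000696	L-Methionine	C5H11NO2S
HMDB0000619	Cholic acid	C24H40O5
HMDB0000172	L-Isoleucine	C6H13NO2
HMDB0000479	3-Methylhistidine	C7H11N3O2
HMDB0000660	Fructose	C6H12O6
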