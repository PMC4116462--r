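pathway_id	name	members
P01	amino acid pool (synthetic)	C001,C002,C003,C004,C005,C006,C007,C008,C009,C010,C011,C012,C013,C014,C015,C016,C017
P02	tryptophan degradation (synthetic)	C017,C022,C040
P03	serotonin and melatonin biosynthesis (synthetic)	C017,C021,C020,C024
P04	monoamine neurotransmitters (synthetic)	C018,C019,C020,C023
P05	carnitine shuttle (synthetic)	C025,C026
P06	glycolysis and feeders (synthetic)	C027,C028,C029,C030,C031
P07	TCA intermediates (synthetic)	C032,C033,C030
P08	glycerophospholipid metabolism (synthetic)	C034,C035,C036,C037,C038,C039
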