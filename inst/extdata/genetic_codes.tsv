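table_id	name	aa	starts
1	Standard	FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG	---M------**--*----M---------------M----------------------------
4	Mold/Protozoan/Mycoplasma	FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG	--MM------**-------M------------MMMM---------------M------------
11	Bacterial/Archaeal/Plant Plastid	FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG	---M------**--*----M------------MMMM---------------M------------
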