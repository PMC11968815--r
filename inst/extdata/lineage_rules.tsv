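taxid	domain	table_id	note
2	Bacteria	11	Bacteria root
2157	Archaea	11	Archaea root
2759	Eukaryota	1	Eukaryota root (nuclear)
10239	Viruses	1	Viruses root
544448	Bacteria	4	Mycoplasmatota (TGA = Trp)
186328	Bacteria	4	Entomoplasmatales
2093	Bacteria	4	Mycoplasma
2132	Bacteria	4	Spiroplasma
9606	Host	NA	Homo sapiens
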