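species_code	alias
hsa	Homo sapiens
hsa	H. sapiens
hsa	human
hsa	humans
mmu	Mus musculus
mmu	M. musculus
mmu	mouse
mmu	mice
mmu	murine
rno	Rattus norvegicus
rno	R. norvegicus
rno	rat
rno	rats
dme	Drosophila melanogaster
dme	D. melanogaster
dme	Drosophila
dme	fruit fly
cel	Caenorhabditis elegans
cel	C. elegans
cel	nematode
dre	Danio rerio
dre	D. rerio
dre	zebrafish
ath	Arabidopsis thaliana
ath	A. thaliana
ath	Arabidopsis
bta	Bos taurus
bta	B. taurus
bta	bovine
bta	cattle
gga	Gallus gallus
gga	G. gallus
gga	chicken
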