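species_code	family_key	gene_name	gene_accession
hsa	let-7	let-7a-1	SYNMI00001
hsa	let-7	let-7a-2	SYNMI00002
hsa	let-7	let-7a-3	SYNMI00003
hsa	let-7	let-7b	SYNMI00004
hsa	let-7	let-7c	SYNMI00005
hsa	let-7	let-7d	SYNMI00006
hsa	let-7	let-7e	SYNMI00007
hsa	let-7	let-7f-1	SYNMI00008
hsa	let-7	let-7f-2	SYNMI00009
hsa	let-7	let-7g	SYNMI00010
hsa	let-7	let-7i	SYNMI00011
hsa	mir-21	mir-21	SYNMI00012
hsa	mir-133	mir-133a-1	SYNMI00013
hsa	mir-133	mir-133a-2	SYNMI00014
hsa	mir-133	mir-133b	SYNMI00015
hsa	mir-214	mir-214	SYNMI00016
hsa	mir-221	mir-221	SYNMI00017
hsa	mir-222	mir-222	SYNMI00018
hsa	mir-451	mir-451a	SYNMI00019
hsa	mir-451	mir-451b	SYNMI00020
hsa	mir-9718	mir-9718	SYNMI00021
hsa	mir-499	mir-499a	SYNMI00022
hsa	mir-29	mir-29a	SYNMI00023
hsa	mir-29	mir-29b-1	SYNMI00024
hsa	mir-29	mir-29b-2	SYNMI00025
hsa	mir-16	mir-16-1	SYNMI00026
hsa	mir-16	mir-16-2	SYNMI00027
mmu	let-7	let-7a-1	SYNMI00101
mmu	let-7	let-7a-2	SYNMI00102
mmu	let-7	let-7b	SYNMI00103
mmu	mir-21	mir-21a	SYNMI00104
mmu	mir-1	mir-1a-1	SYNMI00105
mmu	mir-1	mir-1a-2	SYNMI00106
mmu	mir-1	mir-1b	SYNMI00107
dme	bantam	bantam	SYNMI00201
dme	iab	iab-4	SYNMI00202
dme	iab	iab-8	SYNMI00203
dme	mir-133	mir-133	SYNMI00204
cel	let-7	let-7	SYNMI00301
cel	lin-4	lin-4	SYNMI00302
cel	lsy-6	lsy-6	SYNMI00303
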