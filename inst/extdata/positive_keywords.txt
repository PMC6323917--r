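# Functional keyword stems (positive score). Matched case-insensitively
# at word-prefix boundaries: "regulat" hits regulates/regulated/regulation.
express
overexpress
target
regulat
upregulat
downregulat
inhibit
suppress
repress
promot
activat
induc
silenc
proliferat
apopto
differentiat
migrat
invasi
angiogene
metasta
tumorigen
oncogen
pathway
signaling
signalling
bind
modulat
mediat
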