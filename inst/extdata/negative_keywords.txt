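# Measurement / calculation / procedure keyword stems (negative score).
measur
calculat
quantif
normaliz
normalis
qpcr
rt-pcr
qrt-pcr
pcr
blot
assay
incubat
transfect
centrifug
pipett
plotted
plott
clone
cloned
primer
microarray
luciferase
fold-change
cq
ct-value
amplif
electrophore
stain
fixed
buffer
dilut
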