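# Curated scientific stop terms removed from word clouds: common in any
# molecular-biology sentence, they obscure the functional vocabulary.
# The first four are the canonical examples; the rest are curated
# extensions and the list is meant to be refined over time.
expressed
cell
sequence
gene
cells
genes
sequences
expression
mirna
mirnas
microrna
micrornas
mir
study
studies
data
results
result
figure
table
analysis
analyses
level
levels
shown
showed
show
observed
found
using
used
use
also
may
however
significantly
significant
respectively
compared
experiment
experiments
sample
samples
group
groups
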