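# igsom

Interconnected growing self-organizing maps (I-GSOM) for modeling the
joint acquisition of auditory and semantic categories in early language
learning.

## The problem and who this is for

A child learning words must solve three coupled problems at once: carve
continuous speech sounds into categories, carve meanings into categories,
and associate the two. `igsom` implements a neurocomputational model of
this process for researchers in computational phonetics, developmental
modeling and self-organizing neural networks: two *growing*
self-organizing lattices — an auditory map trained on Bark-scale
spectro-temporal activation matrices of single syllables, and a semantic
map trained on binary word-feature vectors — coupled by trainable,
forgettable associative links. Unlike a fixed-size SOM, a growing map
starts with four nodes and adds nodes at boundary positions whenever a
node's accumulated quantization error exceeds a growth threshold, so
network capacity tracks vocabulary growth without catastrophic
interference.

## The model in brief

Per node $i$ in the BMU's neighborhood, with $d_i$ the lattice distance
from the best matching unit:

$$\omega_i(t+1) = \omega_i(t) + R_\mathrm{learn}(t)\,
  e^{-d_i^2/2\sigma(t)^2}\,(x(t)-\omega_i(t)),$$

with $R_\mathrm{learn}(t+1) = \alpha\,(1 - Q/n(t))\,R_\mathrm{learn}(t)$
($Q = 3.8$, $n$ = node count) and $\sigma(t) = \beta\,\sigma(t-1)$. A
boundary node whose accumulated error exceeds $T_\mathrm{grow}$ grows new
nodes at all free adjacent positions; a saturated interior node
distributes its error to its neighbors. Links between co-activated BMUs
are created at weight 0.1, reinforced by $L = 0.1$, and decay at every
phase end by the relative growth of the possible-link count
$N_\mathrm{link} = n_\mathrm{audio} \times n_\mathrm{semantic}$:
$\omega_\mathrm{link} \leftarrow \omega_\mathrm{link}\,
(1 - (N(t) - N(t-1))/N(t))$.

Training: one basic growing pass, then 15 cycles of reinforcing (tokens
at high-density nodes: more than 4 items or mean distance above 2.5) and
reviewing (full corpus) — 31 steps — then 15 experiment cycles with or
without a reinforcing-by-link phase that re-presents currently
misperceived sound–meaning pairs. A non-mutating checking pass assigns
tokens to BMUs and scores the perceiving path: the strongest link leaving
each solid auditory node is correct iff it reaches a node hosting the
paired word. See `vignette("igsom-methods")` for the full account.

## Worked example

```r
library(igsom)

# Reduced synthetic corpus: 10 syllables x 3 realizations, 3 categories
corp <- syntheticCorpus(syntheticConfig(nSyllables = 10, nCategories = 3,
                                        timeFrames = 20, seed = 42))
corp
#> IGsomCorpus: 30 tokens (10 syllables x 3 realizations), 10 words x 77 features, 20 time frames

cfg <- defaultSchedule(seed = 1, fundamentalCycles = 5)
model <- igsomModel(nrow(audioMatrix(corp)), ncol(semanticMatrix(corp)),
                    seed = 1)
res <- runFundamentalTraining(model, corp, cfg)
tail(res$metrics[, c("step", "phase", "nodesAudio", "nodesSem",
                     "avgItemsSem", "boundaryRatioSem", "linkAccuracy")], 3)
#>    step       phase nodesAudio nodesSem avgItemsSem boundaryRatioSem linkAccuracy
#> 9     9   reviewing         92       40           1            0.475    0.6400000
#> 10   10 reinforcing         92       40           1            0.475    0.7083333
#> 11   11   reviewing         98       40           1            0.475    0.7241379
```

After 11 steps the semantic map hosts each of the 10 words on its own
node (`avgItemsSem` = 1), its boundary-node ratio has fallen from the
initial 1.0 to 0.475 (the lattice is compacting), and the fraction of
solid auditory nodes whose strongest link retrieves the correctly paired
word has risen to 0.72. Continuing with `runExperiment()` and
`withLinkTraining = TRUE` drives link accuracy higher than the same
cycles without link training.

At the default scale (70 syllables x 3 realizations, 24 x 57 = 1368
auditory inputs) the full 31-step fundamental run plus 15 experiment
cycles takes about 7 minutes on one CPU; the semantic map settles around
390 nodes resolving all 70 words.

A command-line wrapper ships in `inst/scripts/igsom`
(`igsom synth | preprocess | train | check | export-plots`), covering
corpus synthesis, WAV-to-Bark preprocessing of annotated recordings,
training with metrics CSV output, model checking, and curve export.

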