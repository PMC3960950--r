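---
title: "Interconnected growing self-organizing maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interconnected growing self-organizing maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igsom)
```

## The model

`igsom` implements a neurocomputational model of how auditory and semantic
categories are acquired jointly during early language learning. Two growing
self-organizing maps (GSOMs) — an auditory lattice trained on 24-Bark-band
by time activation matrices of single syllables, and a semantic lattice
trained on binary word-feature vectors — are coupled by weighted
associative links between co-activated best matching units (BMUs). Unlike
a classical SOM, a GSOM has no fixed size: it starts from a 2-by-2 block
of nodes with uniform random weights in $[0,1]$ and adds nodes at boundary
positions whenever a node's accumulated quantization error
$E_\mathrm{acc}$ exceeds a growth threshold $T_\mathrm{grow}$. This makes
the lattice capacity scale with the knowledge it encodes, avoiding the
catastrophic interference that a fixed-size map suffers when new
vocabulary arrives.

Per presented token the update rule for node $i$ in the neighborhood $N$
of the BMU is

$$\omega_i(t+1) = \omega_i(t) + R_\mathrm{learn}(t)\, h(t)\,
  (x(t) - \omega_i(t)), \qquad
  h(t) = \exp\!\left(-\frac{d_i^2}{2\sigma(t)^2}\right),$$

with $d_i$ the *lattice* (grid) distance of node $i$ from the BMU and
$\sigma(t)$ the current neighborhood size. The learning rate decays as
$R_\mathrm{learn}(t+1) = \alpha\,\phi(n)\,R_\mathrm{learn}(t)$ with
$\phi(n) = 1 - Q/n(t)$, $Q = 3.8$ (just below the 4 starting nodes) and
$n(t)$ the map's current node count, so larger maps learn more slowly per
step; $\sigma(t) = \beta\,\sigma(t-1)$. Both quantities reset to their
initial values for every new token, and the inner loop repeats until
$\sigma$ drops below 1 — exactly 7 iterations at the default
$\sigma_0 = 2$, $\beta = 0.9$.

Associative links are created between the two BMUs of a paired token with
weight $0.1$ and reinforced by $L = 0.1$ per further co-activation
($\omega_\mathrm{link}(t+1) = \omega_\mathrm{link}(t) + L$). At every
phase end, links *forget*: with $N_\mathrm{link}$ the product of the two
maps' node counts (16 initially), the rate
$\Delta\omega_\mathrm{link} = (N_\mathrm{link}(t) -
N_\mathrm{link}(t-1)) / N_\mathrm{link}(t)$
scales every link weight by $1 - \Delta\omega_\mathrm{link}$. Forgetting
counteracts the head start of early-formed links: both maps reorganize as
they grow, so a link formed early points at nodes that may no longer
represent the paired items.

### Training schedule

Training follows four regimes, all parameterized by
`PhaseParams` (defaults shown by `defaultSchedule()`):

| regime | $R_\mathrm{learn}$ | $\sigma_0$ | $T_\mathrm{grow}$ | $\alpha$ | $\beta$ | $\gamma$ |
|---|---|---|---|---|---|---|
| basic growing | 0.5 | 2 | 2 | 0.9 | 0.9 | 0.5 |
| reinforcing | 0.8 | 2 | 1 | 0.9 | 0.9 | 0.5 |
| reviewing | 0.5 | 2 | 2 | 0.9 | 0.9 | 0.5 |
| reinforcing-by-link | 0.8 | 2 | 1 | 0.9 | 0.9 | 0.5 |

*Fundamental training* is one basic growing pass over the full corpus
followed by 15 cycles of reinforcing (tokens selected at high-density
nodes: more than 4 distinct items, or mean node-to-item distance above
2.5, on either map) and reviewing (the full corpus again) — 31 steps.
The *experiment* stage continues for 15 further cycles, optionally
prepending a reinforcing-by-link phase that re-presents exactly those
pairs whose auditory BMU currently carries an incorrect winner link.
During checking with link training active, only the top 20% of link
weights are considered (`linkCheckFraction`), because masses of weak
links otherwise dilute winner selection.

*Checking* never mutates the model: every token is assigned to its BMU on
each map, per-node densities and mean distances are collected, and for
each solid auditory node the winner (maximum-weight) outgoing link is
marked correct exactly when its target node hosts a word paired with a
syllable hosted at the source node.

## Design choices where the procedure was open

* **Neighborhood distance.** The prose description of $h(t)$ reads as the
  distance between the BMU's weight vector and the input, which would
  make $h$ constant over the whole neighborhood and make the notion of a
  "neighborhood size" in grid units vacuous. We use the standard SOM
  interpretation — lattice distance between node $i$ and the BMU — which
  is consistent with the $\sigma \ge 1$ stopping rule. Nodes within grid
  distance $\lceil\sigma\rceil$ participate.
* **Growth bookkeeping.** When a boundary BMU grows, one node is added at
  every free von Neumann neighbor; its weight extrapolates across the BMU
  from the opposite neighbor ($2\omega_\mathrm{bmu} - \omega_\mathrm{opp}$,
  clamped to $[0,1]$), falling back to the first other occupied direct
  neighbor in (row, col) order, then to a plain copy of the BMU weight.
  The grown BMU's accumulated error resets to 0 — otherwise it would
  re-trigger growth on every subsequent token. Growth is checked once per
  token, before the inner loop, per the pseudocode's if/else structure;
  the prose alternative (recheck growth on every inner iteration) was
  rejected as the algorithm box is the normative artifact.
* **Error accumulation** uses the post-update BMU-to-input distance, per
  the pseudocode's operation order, and is re-accumulated on each inner
  iteration. Mid-loop, a node whose error crosses $T_\mathrm{grow}$ stops
  updating; if interior, it distributes error (to $T_\mathrm{grow}/2$,
  neighbors $+\gamma T_\mathrm{grow}$).
* **Link updates in the inner loop.** The pseudocode nests the link block
  inside each map's loop, which would double-count one co-activation. We
  reinforce once per inner iteration whenever at least one map performed
  a weight update that iteration — a link joins one BMU pair.
* **Ties.** BMU search, winner links and the top-fraction filter break
  exact ties lexicographically by grid position, making every run
  reproducible bit for bit from the seed.
* **Solid nodes without links.** A solid auditory node with no (retained)
  outgoing link is marked incorrect — perceiving retrieves nothing for
  it. If the registry holds no links at all, accuracy is undefined (NA)
  rather than zero.
* **$\phi(n)$ floor.** Defensively, $1 - Q/n \le 0$ clamps to 0.01 with a
  warning; after initialization $n \ge 4 > Q$ makes this unreachable.
* **Item counting.** For the high-density selection rule, an auditory
  node's density counts distinct syllables by default (a switch,
  `countRealizations`, counts individual realizations instead — the
  wording "audio data segments" is ambiguous). The summary metric
  "items per solid node" counts audio sequences (realizations) on the
  auditory map and words on the semantic map, matching the corpus totals
  (210 and 70 at default scale).

## Audio preprocessing

Annotated syllable waveforms (mono, 44.1 kHz, with the obstruction
release marked) become 24-by-$T$ activation matrices through:
first-order differencing (a 6 dB/oct high-pass suppressing fundamental
frequency interference); release-aligned zero padding of pre- and
post-release spans to the corpus maxima (comparability therefore holds
only within a corpus); per-signal amplitude normalization; magnitude
spectra of 256-sample Hamming frames hopped every 45 samples (window
≈5.8 ms, hop ≈1 ms) zero-padded to a 2048-point FFT; conversion to dB re
$2\times10^{-5}$ clipped to $[60, 100]$; per-signal normalization;
pooling of FFT bins into the 24 Zwicker critical bands (edges 0, 100, …,
15 500 Hz; bins above 15.5 kHz discarded) and of frames in groups of 10
(final partial group averaged over its own size); and a final per-signal
normalization to $[0,1]$. A corpus whose padded signals span ~25 880
samples yields $T = 57$ and hence $24 \times 57 = 1368$ activation
entries per syllable. Base-10 logarithms are used throughout (dB
convention); constant signals normalize to all-zero (silence semantics).

## The synthetic corpus generator

Real single-syllable recordings and hand-elicited semantic feature sets
of the kind this model is built for are rarely redistributable, so the
package ships a generator that emulates their statistical structure; it
is first-class, tested code, and everything it produces is labelled
synthetic.

* **Audio.** Each of 70 syllable types (5 V + 45 CV + 20 CCV from 5
  vowels and 9 consonants) is a noise-free 24×57 template of 2–3
  Gaussian-profile horizontal bands: vowel identity fixes the steady
  band rows (formant analogs, low vowels high rows), consonant manner
  (plosive burst / nasal / lateral patterns) fixes the onset, and band
  centers move linearly through the transition. Active spans grow from V
  to CV to CCV, making duration a real category cue. Realizations add
  i.i.d. Gaussian noise (sd 0.02 by default — small relative to the
  band amplitude ~0.9, keeping realizations nearest their own template)
  and a ±1-column time shift. Templates are deterministic; realization
  noise, semantics and pairing draw from one seeded stream.
* **Semantics.** 70 words in 9 balanced categories; each word sets its
  category's 25 shared features, 2 word-specific features and sparse
  cross-category bits (probability 0.02), giving 365 raw features — the
  same order as the hand-built set. Features occurring once are pruned
  unless their removal would collapse two words.
* **Pairing.** A seeded random bijection; the three realizations of a
  syllable share one pairing. A pronunciation-similarity heuristic is
  not reproducible without the original lexicon, and the mapping is
  arbitrary by design.

What the generator does *not* emulate: speaker variability, coarticulation
beyond a single linear transition, corpus word-frequency weighting
(presentation is uniform), or the semantic idiosyncrasies of a real
feature elicitation. Passing tests on this corpus therefore demonstrate
algorithmic correctness and qualitative behavior (growth, disambiguation,
link learning), not performance on real recordings.

## Problem sizes used in the tests and the acceptance script

* Unit and property tests run on hand-built lattices and a reduced corpus
  (10 syllables × 3 realizations, 3 categories, 20 time frames), which
  generates in well under a second.
* Parameter recovery runs fundamental training scaled to 5 cycles on the
  reduced corpus: all 10 words resolve to distinct semantic BMUs, the
  average words per solid node reaches 1, and both boundary ratios fall
  from their initial 1.0.
* The reinforcing-by-link comparison runs at 30 syllables × 3
  realizations (5 categories) with the full 15 + 15 cycle schedule. The
  choice of scale is substantive: on the 10 × 3 corpus both experiment
  arms saturate near 100% link accuracy, so the contrast the comparison
  is about — a baseline that stalls below ~90% and is lifted by
  reinforcing-by-link — only exists at a scale with more sound–meaning
  pairs than the maps disambiguate spontaneously. At 30 × 3 the
  fundamental stage stalls around 84%, the regime the comparison is
  meant to probe, and both arms are compared with the same unfiltered
  checking pass
  (the top-20% filter still governs the with-arm's training-time
  checking; comparing a filtered against an unfiltered measurement would
  confound the filter with the training effect).
* The default-scale run (70 × 3 tokens, 1368-dimensional auditory
  inputs, 31 fundamental steps plus 15 experiment cycles) completes in
  about 7 minutes on one CPU and reproduces the qualitative curves:
  node counts grow monotonically and saturate, boundary ratios decline,
  words per solid semantic node reach 1 (all 70 words resolved), and
  link accuracy rises.

## Numerical and degenerate-input conventions

Weights always stay in $[0,1]$: the Gaussian update is a convex
combination, and extrapolated new-node weights are clamped. Link weights
are strictly positive and never pruned; forgetting preserves their
relative order exactly. Empty reinforcing selections skip the phase as a
no-op (the forgetting rate is then 0 if nothing grew). Token presentation
order is corpus order for growing/reviewing and selection order for the
reinforcing regimes; no shuffling anywhere, so two runs with the same
seeds are identical. Model archives store doubles with 17 significant
digits and round-trip bit for bit.

## Known limitations

Growth is undirected ("blind"): nodes appear at every free neighbor of a
saturated boundary node, producing some redundant nodes, and nodes can
never be inserted into the lattice interior. Only the perceiving path
(auditory → semantic) is checked; the production direction is not
modeled. Multi-syllable words, speaker normalization and incremental
vocabulary schedules are out of scope.
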