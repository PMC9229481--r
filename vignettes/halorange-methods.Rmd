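---
title: "Methods: host-range screens, motif avoidance, and Markov-jump signal tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-range screens, motif avoidance, and Markov-jump signal tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halorange)
```

halorange implements the three computational stages behind virus–host
screening studies of halophilic archaea: building a plaque-confirmed
host-range matrix with efficiency of plating, quantifying
restriction-site avoidance in viral genomes, and testing whether host
infectivity carries phylogenetic signal on gene trees. This vignette
explains the models and conventions behind each stage, the parameters
that matter, what the simulators emulate, and the design choices made
where more than one reasonable option existed.

## 1. Plaque-confirmed host-range matrices

The screening design is two-staged: lysate drops are spotted on host
lawns (spot-on-lawn assay), and every pair showing growth inhibition is
re-tested with a quantitative double-layer plaque assay. Haloarchaeal
lysates frequently carry halocins — antimicrobial proteins that clear a
lawn without any infection — so inhibition alone is not evidence of a
virus–host pair. The calling rule is therefore strict:

* plaques observed → **positive** (regardless of the spot result);
* spot inhibition without plaques → **halocin_suspect**;
* neither → **negative**; no assay → **untested**.

`call_interaction()` encodes exactly this truth table, and
`build_host_range_matrix()` applies it to a long assay table. Titer
cells accept both `1.2e9` and `1.2 x 10^9` notations, `-` for
below-detection and `nd` for not-done; below-detection is kept distinct
from zero so that an efficiency of plating (EOP) on such a cell is
reported as absent (with an optional upper bound when a detection limit
is supplied) rather than as 0.

EOP is the titer ratio test host / reference host. Published tables
report it to one significant figure; `round_signif1()` rounds the
mantissa with halves away from zero, which reproduces all ten printed
EOP values in the screening table shipped under `inst/extdata/`
(`6 x 10^-6` through `3`). Genome-identical isolates (known from
sequencing, supplied as metadata, never computed here) are collapsed by
`dedup_unique()` only when a group contributes more than one positive.

## 2. Motif avoidance and the tetranucleotide signature

Hosts with restriction–modification (RM) systems cleave viral DNA at
short recognition sites, and viral genomes under this pressure evolve
to avoid those sites. Absence of a tetramer is easy to see; *partial*
avoidance needs a null expectation. We use the Karlin-style
tetranucleotide relative abundance with maximal-order expectation:

$$\tau(abcd) = \frac{f(abcd)\, f(bc)}{f(abc)\, f(bcd)}$$

with all word frequencies computed on the genome symmetrized with its
reverse complement (counts of $w$ plus counts of $w$ on the
reverse-complemented sequence, over the matching number of valid
windows), so $\tau$ is strand-invariant — appropriate for
double-stranded restriction targets. Under an order-2 Markov null
$\tau \approx 1$; the conventional under-representation cut-off
$\tau < 0.78$ is exposed as an argument. Both the statistic and the
threshold follow the established genome-signature literature; on
i.i.d. 100-kb genomes no tetramer is flagged, and a genome generated
with a motif excised gives $\tau = 0$ for it.

Counting conventions: occurrences are counted with an overlapping
sliding window; windows containing ambiguity codes never match and are
excluded from frequency denominators; genomes are treated as linear
(no wraparound). Motifs longer than four bases (candidate methylation
targets such as GCGCTG) are summarized by density per kb only — the
order-3 expectation behind a 6-mer version of $\tau$ would need far
longer sequences to be stable.

`conserved_column_scan()` covers the complementary protein-level
question: given an alignment of homologs, where does a focal sequence
deviate from an otherwise conserved column? Conservation is computed
over non-focal, non-gap residues; a column needs a *unique* majority
residue (ties are skipped) at or above `min_conservation` (default
0.9), and reports carry both the 1-based alignment column and the
ungapped position in the focal sequence, because substitution labels
like "T380A" refer to ungapped coordinates.

## 3. The Markov-jump signal test

Host infectivity is coded as a binary tip trait (1 = infects the focal
host) on a rooted gene tree, evolving under the symmetric two-state
continuous-time Markov chain with rate $\mu$ and stationary
distribution $(1/2, 1/2)$:

$$P_{\text{same}}(t) = \tfrac{1}{2}(1 + e^{-2\mu t}), \qquad
  P_{\text{diff}}(t) = \tfrac{1}{2}(1 - e^{-2\mu t}).$$

`prune_likelihood()` is the standard pruning recursion with underflow
rescaling; it matches exhaustive enumeration over internal states to
1e-10 and sums to 1 over all tip assignments.

**Stochastic character mapping.** Complete histories conditional on
the tips are drawn in two steps: internal node states by backward
pruning / forward sampling (exact joint conditional), then an
endpoint-conditioned path on every branch by uniformization. For this
chain the uniformized transition kernel at dominating rate $\mu$ is the
deterministic flip, so virtual jumps equal real jumps and the jump
count on a branch is a parity-constrained Poisson: even when the
endpoints agree, odd otherwise, with
$E[N] = \mu t \tanh(\mu t)$ and $\mu t \coth(\mu t)$ respectively.
Change times given the count are sorted uniforms. The samplers are
verified against these closed forms, against exact enumeration on small
trees, and against an independent mapping implementation.

**Rate handling.** The trait rate is not known. A maximum-likelihood
point estimate (`ml_rate()`, log-scale golden-section search on
$[10^{-6},\, 100\,n/T]$ with $T$ the total tree length) is provided and
recovers a generating rate of 0.5 with shrinking error as trees grow.
But conditioning every map on the point estimate understates
uncertainty badly when tip states carry little rate information: across
tip permutations of one 32-tip tree the ML rate ranges over two orders
of magnitude, and the resulting jump HPDs are narrow and mutually
disjoint, so a permutation test built on them rejects far too often
(measured type-I error ~14% against a nominal HPD-overlap criterion).
`signal_test()` therefore defaults to *marginalizing* the maps over a
discretized rate posterior (`rate_posterior()`: 61 log-spaced grid
points on the same bracket, uniform-in-log prior, weights proportional
to the pruning likelihood). This mirrors how a fully Bayesian analysis
summarizes Markov jumps over the joint posterior of rate and history,
and restores honest interval widths: rate-uncertain datasets get wide
jump distributions. The ML-conditioned variant remains available as
`rate = "ml"`.

**The test.** The real run yields a Markov-jump sample and its 95% HPD
(`hpd()`: shortest contiguous window containing
$\lceil 0.95 n \rceil$ sorted points, ties toward the smaller lower
bound). Each of 10 null runs permutes the states across tips
(preserving state counts — the exchangeability null) and repeats the
entire procedure including rate estimation. The decision rule is a
documented convention: **no_signal** iff the real HPD intersects at
least one null HPD, **signal** iff it is disjoint from all of them;
per-run overlap flags are always reported so the reader can apply a
stricter or looser rule. Monomorphic traits give a degenerate result
with no decision. When several trees are supplied (e.g. a posterior
tree sample) the map samples are split equally across trees and pooled,
with the rate re-estimated per tree.

## 4. What the simulators emulate

* `simulate_yule_tree()` — pure-birth trees (ultrametric, exponential
  waiting times). Real gene trees from coalescent-style analyses are
  not Yule, but the signal test is agnostic to tree provenance and the
  Yule process is simple to verify (fixed-time runs reproduce
  $E[N(t)] = 2e^{bt}$).
* `simulate_trait_history()` — forward simulation of the symmetric
  chain with the full change history retained, so the true jump count
  is available as ground truth (mean total jumps $= \mu \times$ total
  tree length).
* `simulate_clade_structured()` — the positive control: a Yule tree
  conditioned on a balanced root bipartition (each side at least one
  third of the tips), root-adjacent branches lengthened by 10 (several
  times the height of a rate-1 Yule tree), trait = root bipartition.
  Balance is part of the definition: a one-tip "clade" is matched by
  random permutations and carries essentially no signal, so
  unbalanced splits would dilute a power study with undetectable
  datasets.
* `simulate_avoided_genome()` — i.i.d. or first-order Markov genomes
  with avoided motifs removed by local window resampling (pure
  rejection would be hopeless at realistic lengths); avoidance is
  verified post hoc. The generator takes dinucleotide frequencies,
  which determine a first-order chain — that is the model actually
  identifiable from them, so the supported orders are 0 and 1.
* `simulate_infection_tables()` — the two-stage screen with defaults
  matching the motivating study's design: 95 viruses x 14 hosts,
  susceptibility probability 0.0075 (≈10 positives per screen),
  log10-normal titers (mean 9, sd 1, spanning the observed
  $10^3$–$10^{12}$ pfu/mL), and a 5% halocin false-positive rate for
  the spot assay (the study reports "several cases"; no rate is
  published). By construction the plaque-confirmation rule recovers
  the truth matrix exactly for any halocin rate — the simulator tests
  the calling logic, not assay noise, which is out of scope.

What passing these simulations does *not* show: robustness to
misrooted or misestimated trees, to lysogenic infections invisible to
plaque assays, or to compositional heterogeneity along real genomes.
Real-data conclusions inherit those caveats.

## 5. Numerical choices and problem sizes

* Likelihood rescaling triggers below 1e-150 per node; the rate search
  uses tolerance 1e-7 on $\log\mu$.
* The parity-constrained Poisson sampler inverts the series for
  $\lambda < 20$ (vectorized) and switches to rejection from the
  unconstrained Poisson above (acceptance ≈ 1/2).
* Zero-length branches are allowed; a path request with unequal
  endpoints on a zero-length branch is an error.
* The operating-characteristic study in the test suite uses 100
  permutation-null datasets and 50 clade-structured datasets on 32-tip
  trees with 250 map samples per run and 10 null runs per dataset;
  `analysis/04_operating_characteristics.R` runs a smaller
  reporting-sized version (40/25 datasets), and the acceptance script
  60/30. At these sizes the measured rates (null no_signal and
  structured signal both ≈100%) are stable well beyond the 95%/90%
  planning targets.
* Map samples default to 1000 per run in `signal_test()`; the
  simulation studies use 250, which leaves the HPD endpoints of
  integer-valued jump distributions essentially unchanged.

## 6. Known limitations

* Two states and a symmetric rate matrix only, by design; the
  asymmetric and multi-state generalizations change the uniformization
  step (virtual jumps no longer equal real jumps).
* The tetramer statistic needs all component words present; very short
  or extremely biased sequences return a flagged, non-evaluable
  signature rather than a number.
* The HPD-overlap decision is conservative by construction (one
  overlapping null run suffices for "no_signal"); users wanting a
  p-value-style summary should inspect the per-run flags and the raw
  jump samples that the result object carries.
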