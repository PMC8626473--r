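---
title: "Quantifying gene-tree discordance and dating genome duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-tree discordance and dating genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodisc)
```

## The problem

When a clade radiated rapidly — as the five major mesangiosperm lineages
(eudicots, monocots, magnoliids, Chloranthales, Ceratophyllales) did —
individual nuclear gene trees disagree with each other and with the species
tree. Two biological processes produce such discordance: incomplete lineage
sorting (ILS), the stochastic persistence of ancestral polymorphism across
short internal branches, and hybridization/introgression between
non-sister lineages. Telling them apart matters because they imply different
evolutionary histories. `phylodisc` implements a desk-scale pipeline for this
question: a discordance census, two complementary introgression tests, a
simulation-based false-positive control, and — because ancient
whole-genome duplications (WGDs) are part of the same genomic histories — a
node-weighted Ks clock for dating duplications and LTR insertions.

All inputs can be generated synthetically, so every stage is testable
without any sequencing data.

## The multispecies coalescent simulator

Gene trees are simulated under the multispecies coalescent (MSC) on a rooted
species tree or network. Time is measured in coalescent units (2N
generations). Within a population carrying $k$ lineages the waiting time to
the next coalescence is $\mathrm{Exp}\!\left(\binom{k}{2}\right)$ and the
merging pair is uniform; at a reticulate node each lineage independently
follows a parent edge with its inheritance probability $\gamma$; all
remaining lineages coalesce above the root. Output branch lengths are
coalescent units times `mutation_scale` (default 1; the substitution clock
is scale-equivariant for every downstream test, so this only affects
units). Species-tree branch lengths are treated as durations on a shared
clock with contemporaneous tips; the shipped examples are ultrametric.

The key closed form used throughout testing: for a rooted triplet with
internal branch $t$, each discordant resolution occurs with probability
$\tfrac{1}{3}e^{-t}$.

Simulated bootstrap supports default to a constant 100 so that census
support filters are inert on synthetic data; a beta noise model
(`support_model = list(type = "beta", ...)`) is available when support
filtering itself is under study.

For the four-taxon D-statistic model, unlinked biallelic sites are generated
one genealogy at a time under the same MSC with an optional introgression
pulse: with probability $\gamma$ the P2 lineage is moved into P3's
population at time `tau_gf` (default: halfway down the P1–P2 split). A
single mutation is placed uniformly on each genealogy (infinite-sites), so
ABBA/BABA counting needs no sequence-evolution model. The pulse-time default
matters little: any `tau_gf` below the P1–P2 split produces an ABBA excess,
which is all the statistic measures.

## The topology census

Each rooted gene tree is classified by which of three diagnostic clades it
contains, evaluated on the focal tips only (species outside the three focal
groups are ignored, so e.g. Ceratophyllales never blocks a match):

* **Type I** — a clade of all monocot and eudicot tips (the
  Chloranthales+magnoliids group is sister to the rest);
* **Type II** — a clade of Chloranthales+magnoliids plus eudicots;
* **Type III** — a clade of Chloranthales+magnoliids plus monocots.

On a binary tree the three are mutually exclusive. Classification tolerates
non-monophyly of the individual groups; group monophyly is reported as a
separate per-type fraction rather than used as a gate, since published
per-type monophyly fractions below 100% imply the original classification
did the same. The bootstrap filter (default 70) applies to the branch
subtending the diagnostic clade only; where pruning makes several nested
nodes match the same clade, the best-supported one is used. Trees missing a
focal group are skipped with a warning in batch mode. Gene trees are rooted
with `root_by_outgroup()`; how trees were rooted upstream is rarely
reported, so outgroup rooting with a flagged fallback for non-monophyletic
outgroups is this package's convention.

The census denominator is "trees with all three groups present and a
supported diagnostic clade"; no published rule for the excluded remainder
exists, so `census()` reports raw counts, filtered counts and skip counts
separately.

## The triplet branch-length mixture test

For a species triplet with true topology $((A,B),C)$, ILS produces the two
discordant topologies at equal rates with internal branch lengths that are
exponential (memoryless residual of the coalescent). Introgression adds a
second, older cohort of discordant trees. `fit_branch_mixture()` therefore
compares

* $f_1(t) = \lambda^{-1} e^{-t/\lambda}$ (ILS only), MLE
  $\hat\lambda = \bar t$, against
* $f_2(t) = \pi \,\lambda^{-1} e^{-(t-K)/\lambda}\mathbf{1}[t \ge K] +
  (1-\pi)\,\lambda^{-1} e^{-t/\lambda}$, a shared-rate two-component
  mixture whose shifted component (weight $\pi$) is the non-ILS cohort.

The shift $K$ is profiled on a 200-point grid from 0 to the 99th percentile
of $t$; at each $K$ an EM with closed-form M-steps runs to relative
log-likelihood tolerance $10^{-8}$ (cap 500 iterations), best of five
starting weights. Because $\lambda$ is shared, the E-step responsibility is
identical for every observation above the shift, which reduces each EM
iteration to constant time given $\#\{t_i \ge K\}$ — the implementation in
`src/` exploits this. Including $K = 0$ in the grid guarantees the nested
inequality $\log L_2 \ge \log L_1$.

Model choice uses $\mathrm{BIC}_1 = -2\log L_1 + \ln N$ versus
$\mathrm{BIC}_2 = -2\log L_2 + 3\ln N$ with the strict rule
$\Delta\mathrm{BIC} = \mathrm{BIC}_1 - \mathrm{BIC}_2 > 10$ for calling a
mixture. At $N = 500$ this rule's false-call rate on pure exponential data
is well below 5% (the test suite measures it), and detection of a planted
$\pi = 0.5$, $K = 2$ mixture is essentially certain.

`run_triplet_protocol()` repeats the fits over 100 subsamples of 500 trees
(defaults; sampling without replacement within a run, run seeds derived from
one master seed). Fits on discordant topologies are attributed to the
species pair united against the species tree, and the per-pair average
non-ILS rate — the fitted $\pi$, counted as 0 for ILS-only decisions — is
compared with the flag threshold 0.1. The companion ILS/hybridization ratio
$(1-\hat\pi)/\hat\pi$ is reported alongside the raw $\hat\pi$, since the
published "average ratio" was never given as a formula; both are emitted so
either convention can be recovered. Observations below $N = 20$ per
triplet-topology are refused rather than fitted.

## The D-statistic

`count_patterns()` counts, per block of unlinked sites over
$(P_1, P_2, P_3, O)$, the ABBA $(0,1,1,0)$ and BABA $(1,0,1,0)$
derived-allele patterns (outgroup ancestral; genotype-level counting with
one haploid allele per taxon — a read-sampling estimator is out of scope).
Then

$$D = \frac{\sum \mathrm{ABBA} - \sum \mathrm{BABA}}
           {\sum \mathrm{ABBA} + \sum \mathrm{BABA}},$$

with a delete-one block jackknife standard error over the $m$ blocks,
$Z = D/\mathrm{SE}$, and the conventional $|Z| > 3$ significance rule.
Quartets whose arrangement contradicts the species tree are excluded by
`conformity_filter()`. Degenerate cases are errors, not zeros: no
informative sites at all, or all informative sites in one block, leave $D$
or its SE undefined and are reported as such.

## Node-weighted Ks distributions and molecular ages

A family of $n$ paralogs yields $n(n-1)/2$ pairwise Ks values but only
$n-1$ duplication events, so naive pooling over-weights deep nodes. With a
rooted family tree, every duplication node with child clades $L, R$
contributes its $m = |L||R|$ cross-pairs at weight $1/m$: each node
contributes exactly total weight 1, each family $n-1$. Families outside
$1 < n < 5$ are rejected (the low-copy filter that keeps paralog trees
reliable). When no family tree is supplied, UPGMA on the Ks matrix is used —
duplication histories are approximately ultrametric in Ks and family size is
at most 4, so topology error is limited; externally estimated trees can be
passed in instead.

Pairwise Ks values from codon alignments use the Nei–Gojobori counting
estimator with equal-weight pathway averaging (stop-codon pathways
excluded) and the Jukes–Cantor correction; $p_S \ge 0.75$ is a saturation
error. This is a counting surrogate for likelihood Ks estimation, adequate
for peak location at desk scale; per-codon behaviour is pinned to an
independent brute-force oracle in the tests.

The WGD peak is the argmax of a weighted Gaussian KDE on a 0.005-step grid
over $(0.05, 2.0]$ — the lower bound excludes the allelic/tandem spike near
zero. The bandwidth defaults to Silverman's rule on the weighted sample
(effective sample size $(\sum w)^2 / \sum w^2$); the original peak-location
method was never specified, so a published and configurable default was
chosen. Secondary maxima above 25% of the peak height trigger a
multimodality warning.

Ages come from the molecular clock
$$T = \frac{K}{2r}, \qquad r = 1.51 \times 10^{-9}
  \text{ substitutions site}^{-1}\text{yr}^{-1}\ \text{(default)},$$
applied identically to LTR terminal-repeat divergences and Ks peaks, e.g.

```{r ltr}
molecular_age(0.03)            # the LTR burst worked example, in years
round(molecular_age(0.03) / 1e6, 1)
```

## The synthetic-data generator as a study design

`simulate_ks_families()` emulates the structure the Ks pipeline assumes: a
WGD cohort (60% of duplication nodes at Ks 0.9 in the reference
configuration, matching the reported paralog peak) over a uniform
small-scale-duplication background on $(0.05, 2)$, with multiplicative
lognormal noise ($\sigma = 0.1$) and node values ordered so deeper nodes are
older. Family sizes 2:3:4 are drawn at 0.5:0.3:0.2 — a decaying size
distribution typical of low-copy paralog families; the exact split is not
critical and is fixed once here. What the generator does *not* emulate:
rate variation among lineages, Ks saturation noise growing with distance,
and fractionation bias; recovering the planted peak therefore demonstrates
correctness of the weighting and KDE machinery, not robustness to every
property of real paralog data.

The LTR generator is a truncated normal around the burst divergence; the
site-pattern generator is described above. Every generator is deterministic
given its `sim_config(seed)`.

## The false-positive control

`run_fp_control()` simulates ILS-only gene trees under a fixed species tree
(2,329 trees and 10 replicates by default, matching the reference design),
reruns the census and the triplet protocol, and reports the fraction of
replicates with no hybridization flag among the focal pairs; at least 90%
flag-free passes. Under the null the two minor census types are also
expected at equal frequency — the symmetry whose violation in real data
argues against ILS alone. Flag-freedom is judged on the triplet test, this
package's in-scope stand-in for a network-search control; D-statistic null
calibration is covered in its own test suite. Analyses run per replicate
rather than on a pooled tree soup, which keeps replicates independent.

The shipped 18-taxon example tree (`example_species_tree()`) uses 0.5
coalescent-unit conflict branches, giving roughly 40% discordant triplets —
a regime where a miscalibrated test would flag readily.

## Problem sizes and numerical choices

The test suite runs the calibration studies at the sizes stated above:
30,000 trees per branch length for the simulator closed form, 200
replicates of $N = 500$ for mixture calibration and power, 1,000 null
replicates of 200 blocks × 250 sites for D-statistic calibration, 10
replicates × 500 trees for the false-positive control, and 500 families for
Ks peak recovery. These sizes keep Monte-Carlo error well inside the
asserted tolerances. Deterministic tie-breaks: UPGMA input is sorted by
gene id; the KDE mode grid is fixed; EM restarts are a fixed set of starting
weights, so every fit is reproducible without a seed.

## Known limitations

* The census bootstrap filter on a pruned diagnostic clade has no unique
  support value when several nested original branches collapse to one
  pruned edge; the maximum is used.
* The triplet mixture assumes a shared rate between components and a single
  pulse; continuous migration or multiple pulses blur $K$.
* NG86 Ks saturates earlier than likelihood estimators; peaks beyond
  Ks ≈ 1.5 should be treated as qualitative.
* The MSC simulator assumes constant population size per branch and no
  recombination within loci.
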