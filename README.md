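# phylodisc

Quantifying gene-tree/species-tree discordance, separating incomplete
lineage sorting (ILS) from hybridization, and dating whole-genome
duplications (WGDs) and LTR retrotransposon bursts.

Rapid radiations — the textbook case being the five major mesangiosperm
clades (eudicots, monocots, magnoliids, Chloranthales, Ceratophyllales) —
leave nuclear gene trees in conflict with each other and with the species
tree. `phylodisc` is aimed at phylogenomicists who have a set of rooted gene
trees (or want to simulate them) and need to answer, at desk scale: how is
the conflict distributed, is it ILS alone or is there gene flow, and where do
genome duplications fall in time?

## What it computes

* **Topology census.** Each rooted gene tree is classified by the
  arrangement of three focal clades (Type I: clade 1 sister to clades 2+3;
  Type II: clades 1+3 together; Type III: clades 1+2 together), with a
  bootstrap filter (default 70) on the diagnostic clade's subtending branch,
  per-type monophyly fractions, and a chi-square homogeneity test of the
  genes' chromosome distribution across types.
* **Triplet branch-length mixture test.** For each species triplet, internal
  branch lengths of discordant gene-tree topologies are fit with a
  one-component exponential (pure ILS, density `exp(-t/λ)/λ`) versus a
  two-component shared-rate mixture whose shifted component
  `π·exp(-(t-K)/λ)/λ` is a non-ILS cohort; models are compared with a strict
  ΔBIC > 10 rule, resampled over 100 runs × 500 trees, and aggregated into
  per-species-pair hybridization flags (average non-ILS rate > 0.1).
* **ABBA-BABA D-statistic.** `D = (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA)` over
  blocks of unlinked biallelic sites for `(((P1,P2),P3),O)`, delete-one
  block-jackknife SE, `Z = D/SE` with the |Z| > 3 rule, and a species-tree
  conformity filter for quartets.
* **Coalescent false-positive control.** Gene trees simulated under the
  species tree with ILS as the only source of conflict (default 2,329 trees
  × 10 replicates), analyses re-run, hybridization flags counted.
* **Node-weighted Ks distributions.** A family of *n* paralogs gives
  *n(n−1)/2* pairwise Ks values for only *n−1* duplication nodes; each
  node's *m* cross-pairs enter with weight 1/*m*. The WGD peak is the mode
  of a weighted Gaussian KDE, and ages follow the molecular clock
  `T = Ks/(2r)` with `r = 1.51e-9` substitutions/site/year by default —
  the same clock used for LTR insertion ages from 5'/3' terminal-repeat
  divergence. Pairwise Ks from codon alignments uses Nei–Gojobori counting.
* **Synthetic data for all of the above:** a multispecies-coalescent
  simulator on species trees *and networks* (extended newick with `#H`
  reticulations and inheritance probabilities γ), a 4-taxon site-pattern
  simulator with an introgression pulse, Ks gene-family and LTR-divergence
  generators — all byte-reproducible from a seed.

## Worked example

```r
library(phylodisc)

# 1. discordance census on 1,000 gene trees simulated under the shipped
#    18-taxon mesangiosperm species tree (conflict branches 0.5 CU)
sp    <- example_species_tree()
trees <- simulate_msc_gene_trees(sp, sim_config(seed = 1, n_trees = 1000))
census(trees, example_group_scheme())
#> topology census: 1000 trees, 806 typed (BS >= 70), 0 skipped
#>  type count_raw count_bs_pass proportion monophyly_fraction
#>     I       138           138  0.1712159          0.9420290
#>    II       526           526  0.6526055          0.8193916
#>   III       142           142  0.1761787          0.9154930

# 2. D-statistic on simulated site patterns with a gamma = 0.3 pulse
d_statistic(simulate_site_patterns(gamma = 0.3, config = sim_config(seed = 1)))
#> D = 0.7495  (ABBA = 2109, BABA = 302, 200 blocks)
#> jackknife SE = 0.01272, Z = 58.90  *significant*

# 3. recover a planted WGD cohort at Ks = 0.9 from 500 simulated families
fams <- simulate_ks_families(500, wgd_ks = 0.9, wgd_fraction = 0.6,
                             noise_sigma = 0.1, config = sim_config(seed = 1))
ks_peak(do.call(rbind, lapply(fams, weight_family)))
#> weighted Ks peak: mode = 0.890 (bandwidth 0.0381)

# 4. the molecular clock, e.g. the LTR burst at divergence K = 0.03
molecular_age(0.03)          # 9933775 years ~ 9.9 Ma
```

Reading the output: 65% of filtered gene trees here support the
species-tree arrangement (Type II) while ILS alone produces the two minor
types at roughly equal frequency — an asymmetry between Type I and III
would be the hint of gene flow. The D-statistic's Z ≫ 3 correctly detects
the simulated pulse. The weighted-KDE mode (0.890) recovers the planted
Ks = 0.9 cohort; with the default rate that peak converts to an age via
`molecular_age()`.

A command-line wrapper lives at `inst/scripts/phylodisc` with subcommands
`simulate`, `census`, `triplet-test`, `dstat`, `ks-weight`, `ks-peak`,
`ltr-age`, `fp-control` and `report`; every run writes a JSON manifest with
the seed, parameters and artifact checksums.

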