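---
title: "Methods: clonal structure, differentiation and the forward simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal structure, differentiation and the forward simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramets)
```

This vignette documents the models behind the package, the conventions and
numerical choices where the literature leaves room, and what the synthetic
data generator does and does not emulate.

## Data model

A genotype table holds one row per sampled colony (ramet): an id, a site
(population) label, optional planar coordinates in metres, an optional
colour phenotype, and two allele-size columns per microsatellite locus.
Allele pairs are unordered and stored sorted; a locus call is complete or
missing as a unit (half-missing calls are promoted to missing, and `0` or
blank cells are missing on input). The locus panel records each locus's
repeat-motif length in base pairs — required to convert allele-size
differences to mutation steps — and an exclusion flag for loci that should
be kept for clone discrimination but dropped from structure analyses
(typically loci with evidence of null alleles). Colonies carrying a third
allele at a locus are expected to be encoded as missing at that locus
upstream; the table enforces at most two alleles.

## Clone discrimination

Two colonies share an MLG iff all loci carry identical unordered allele
pairs. MLG labels are assigned by decreasing abundance, so `MLG01` is
always the most replicated genotype.

**P_gen and P_SEX.** For a genotype with per-locus allele frequencies
$f_i$ and a single multilocus inbreeding coefficient $F_{IS}$, each
heterozygous locus A/B contributes $2 f_A f_B (1 - F_{IS})$ and each
homozygous locus A/A contributes $f_A^2 + f_A (1 - f_A) F_{IS}$;
`p_gen()` is the product. `p_sex(n, N, p_{gen})` is the probability that
at least $n - 1$ of the other $N - 1$ sampling units independently drew
the same genotype sexually: the upper tail of a
$\mathrm{Binomial}(N - 1, p_{gen})$. Conventions chosen here, where a
reference implementation does not pin them down:

* allele frequencies feeding `p_gen()`/`p_id()` default to the
  *genet-level* (clone-censored) scheme, so large clones do not inflate
  their own allele frequencies; ramet-level counting is available by flag;
* the $F_{IS}$ inserted into $P_{SEX}(F_{IS})$ is the single multilocus
  Weir–Cockerham estimate from the truncated dataset (configurable to the
  entire one), matching the single-parameter notation;
* `p_sex()` uses the "$N-1$ other units" binomial convention; the
  "all $N$" variant differs negligibly and is not offered.

**MLL collapsing.** Somatic mutation and scoring error split true clones
into near-identical MLGs. Distances are counted under the stepwise
mutation model: per locus, the two allele pairs are matched in the pairing
minimising the summed absolute size difference, divided by the motif
length; loci sum. The pairing minimum can violate the triangle
inequality, which is documented rather than "fixed" — the matrix is a
dissimilarity, not a metric. All alleles at a locus must lie on one
repeat ladder (every size difference divisible by the motif); anything
else is a data error naming the locus. The collapse threshold is derived
from the distribution of pairwise inter-MLG distances: the first empty
one-step bin. If the minimum observed distance is already one step there
is no gap separating error from divergence and the threshold is zero (no
collapsing). Collapsing takes single-linkage components of the graph
joining MLGs at or below the threshold, so chains A–B–C merge even when
A–C exceeds it.

## Clonality statistics

With clone sizes $n_1, \dots, n_G$ summing to $N$:

* richness $R = (G - 1)/(N - 1)$ (0 monoclonal, 1 all distinct);
* $G_O = 1/\sum (n_i/N)^2$ and the normalised $G = G_O/N \in (0, 1]$.
  The normaliser $N$ is the expected $G_O$ of a fully sexual sample, which
  makes $G$ span exactly "1 in sexual populations to 0 in clonal ones";
  this is the one place where the reference index family is ambiguous, and
  the choice is recorded here deliberately;
* Simpson evenness $ED^*$ rescales the unbiased Simpson complement
  $D = 1 - \sum n_i(n_i-1)/(N(N-1))$ between the least even configuration
  compatible with $(N, G)$ — one clone of $N-G+1$ plus singletons — and
  the most even (sizes differing by at most one). It is undefined, and
  errors with an explanation, when all clones are singletons or there is a
  single clone;
* the Pareto exponent β is minus the OLS slope of
  $\log(\text{fraction of MLGs of size} \ge x)$ on $\log x$ over the
  distinct observed sizes, one support point per size — the log-log
  cumulative convention. At 500 MLGs this estimator has a sampling sd of
  roughly 0.2 and a small-sample downward bias of about 0.1 for a true
  exponent of 1.5; recovery checks therefore average replicate draws
  rather than judging single draws;
* allelic richness is hypergeometric rarefaction to a common number of
  gene copies, conventionally twice the smallest per-population genet
  count; expected heterozygosity uses Nei's unbiased
  $(2n/(2n-1))(1 - \sum p_i^2)$.

## Spatial statistics

All three statistics require coordinates; populations without them are
skipped with a note, never zero-filled.

The exact normalisations of the classical aggregation and edge-effect
indices are not published; the forms used here satisfy the qualitative
contract and are defined by this package:

* **Ac** compares the nearest-neighbour clonemate fraction $P_{nn}$
  (Euclidean; distance ties resolved by lowest index) with the all-pairs
  fraction $P_{all}$: $A_c = (P_{nn} - P_{all})/(1 - P_{all})$, 0 in
  expectation under label randomness, 1 under complete aggregation.
* **Ee** compares the mean distance to the coordinate centroid of colonies
  carrying singleton MLGs with that of all colonies:
  $E_e = (D_{uniq} - D_{all})/D_{all}$, positive when new genotypes sit
  toward the periphery.
* **Moran's I** is computed per allele on dosages (copies/2) with
  inverse-distance weights collapsed into one distance class — a single
  global statistic per site, not a correlogram — and averaged over alleles
  weighted by dosage variance, which reduces to a single kernel ratio and
  drops zero-variance alleles automatically. Coincident points receive
  the minimum positive inter-point distance as their separation.

Significance is by permutation: MLG labels over fixed coordinates for Ac
and Ee (one-sided), coordinate assignments for Moran's I (two-sided,
doubled smaller tail). All permutation p-values use the $(b+1)/(m+1)$
estimator and a caller-supplied seed, making every report bit-reproducible.
Defaults are 1000 permutations for spatial tests and 10000 for the
F_IS test.

## Differentiation on entire and truncated datasets

Clonal replication biases allele frequencies toward the fittest genotypes.
Both conventions are therefore computed side by side: the *entire* dataset
keeps every ramet; the *truncated* dataset keeps the first
complete-genotype representative of each MLG in each population. Excluded
loci (null-allele flags in the panel) are dropped from these analyses
only.

$F_{IS}$ and pairwise $F_{ST}$ are Weir–Cockerham variance-component
estimators aggregated ratio-of-sums over alleles and loci (the standard
multilocus form). The HWE test shuffles gene copies among individuals
within a population, which preserves allele frequencies, so only observed
heterozygosity varies across permutations; p-values are two-sided.
Pairwise $F_{ST}$ p-values permute individuals between the two
populations (one-sided). Jost's $D_{est}$ uses the harmonic-mean
sample-size correction $2\tilde n/(2\tilde n - 1)$ on within-population
heterozygosity, total heterozygosity from unweighted mean frequencies,
the $r/(r-1)$ factor with $r = 2$, and an arithmetic mean over polymorphic
loci (the harmonic-mean-of-$1/D$ variant is not implemented; on strongly
skewed per-locus D the two can differ, a documented deviation risk).
Genotypic disequilibrium between locus pairs uses the G statistic of the
single-locus-genotype contingency table with one locus's genotypes
permuted, Bonferroni-adjusted across the $\binom{L}{2}$ pairs.
Small negative $F_{ST}$/$D_{est}$ are estimator noise and are reported as
computed; with only a handful of genets per population the $D_{est}$
noise band widens accordingly.

## Ordination and networks

The "PCA on a Dice dissimilarity" tradition is realised as principal
coordinates (Gower double-centering of $-d^2/2$, eigendecomposition,
coordinates scaled by the root eigenvalues). Dice distance treats each
genotype as its set of (locus, allele) bands. Negative eigenvalues —
expected for non-Euclidean dissimilarities — are reported but excluded
from percent-variance denominators. The clone network uses shared-allele
distance (per-locus multiset intersection of allele pairs) and, when no
threshold is given, the percolation threshold: the smallest edge weight at
which the thresholded graph is connected, found by scanning the sorted
unique weights. Exports are edge-list CSV and GraphML; layout is only
computed for plotting, with a fixed seed.

## The forward simulator

`sim_config()` defaults encode the surveyed conditions the package is
designed around: 4 sites of 183/297/50/57 colonies spaced 2–40 km along a
coast, 13 microsatellite loci on motif-2 ladders with 8 alleles, two
genetic clusters at Balding–Nichols divergence $F = 0.2$ (sites 1–2 in
cluster 1, site 4 in cluster 2, site 3 drawing genets 50:50 from both), a
superclone holding 47% of all colonies spread over the cluster-1 and mixed
sites proportionally to site size, remaining clone sizes from a discrete
Pareto law with survival $x^{-\beta}$ ($\beta = 1$ by default, giving the
observed few-large-many-small spectra), genets seeded uniformly in 12
m-radius sampling discs with ramets scattered at $\sigma = 2$ m and
reflected into the disc, a 1% chance per ramet of long-distance transport
to another site, inbreeding $f_{IS} = 0.15$ in genotype draws (the
surveyed range of positive truncated $F_{IS}$), optional one-step stepwise
somatic mutation (off by default, matching the observed absence of
one-step MLG pairs), and a 1% per-locus missing rate (reproducing the
~11% of colonies carrying at least one missing call). One `set.seed` at
entry drives a single RNG stream in documented draw order, so a seed fixes
the whole dataset bit-for-bit.

What the generator does *not* emulate: coalescent ancestry within
clusters (genets are independent draws, so there is no isolation by
distance within sites beyond clonal aggregation), overlapping generations,
fitness differences among genotypes, genotyping artefacts other than
uniform missingness (no allelic dropout or size-binning error), and
triploid calls. Passing recovery tests therefore demonstrates estimator
correctness under the declared model, not robustness to every artefact of
real surveys.

## Numerical choices and degenerate inputs

* Permutation p-values: $(b+1)/(m+1)$, never zero; two-sided tests double
  the smaller tail and cap at 1. Permutation counts of 99/199 give exact
  attainable levels at $\alpha = 0.05$ for one- and two-sided tests in the
  validation suites; production defaults are 1000/10000.
* Degenerate inputs error with explanatory messages rather than returning
  NaN: no clonemates (Ac), no singletons (Ee), all-coincident coordinates
  or no polymorphic allele (Moran), monomorphic loci (F_IS),
  populations of one (F_ST), single support point (Pareto β).
  The pipeline catches these per stage and records them in a failure
  manifest while the remaining stages run.
* The validation suites use deliberately modest problem sizes — 500
  replicates at 50–200 samples for null calibration, 20 replicates of 50
  genets per population for divergence recovery, survey-shaped datasets of
  a few hundred colonies for end-to-end truth recovery — chosen to bound
  each estimator's noise well inside the asserted bands.

## Known limitations

Distances from the per-locus minimal pairing are not metric; MLL
collapsing is single-linkage and can chain through intermediates; the
per-MLG lineage gate assumes intra-MLG lineage homogeneity (one sequenced
representative speaks for its clonemates); the aggregation/edge-effect
normalisations are package-defined as stated above; and $D_{est}$
across loci uses the arithmetic mean only.
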