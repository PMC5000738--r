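---
title: "Dominant-marker population genetics with bandpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker population genetics with bandpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandpop)
```

## The data and its limits

RAPD and ISSR markers are *dominant*: a PCR band is visible whenever an
individual carries at least one amplified allele at a locus, so the observed
datum is a binary phenotype, not a genotype. Heterozygotes and
amplified-allele homozygotes are indistinguishable, and every statistic in
this package is built on that constraint. The universal container is a
`marker_matrix`: individuals × loci entries in {1 = band present, 0 = band
absent, NA = not scored}, a population label per individual, and per-locus
metadata (primer, marker system RAPD/ISSR, fragment size) parsed from locus
identifiers of the form `PRIMER_sizebp`.

Missing cells are defensive rather than expected — gel scoring normally
yields complete matrices — so they are never imputed: frequencies use
locuswise deletion, similarities and distances use pairwise deletion (with
distances rescaled by total/shared locus count so all pairs stay on one
scale), and the cluster model simply drops the likelihood terms. Locus order
is taken from the input file and never sorted, because a dominant marker's
identity is its primer plus approximate fragment size.

## Allele frequencies and diversity

Under Hardy–Weinberg equilibrium the band-absent phenotype is the null/null
homozygote, observed with frequency $q^2$. `estimate_allele_freqs()`
therefore uses $\hat q = \sqrt{x}$ with $x$ the null-phenotype frequency and
$\hat p = 1 - \hat q$; expected heterozygosity is
$H = 1 - (\hat p^2 + \hat q^2) = 2\hat p\hat q$, maximal at $0.5$. The plain
square root is biased upward in small samples, so an optional first-order
Taylor correction $\hat q\,(1 + \mathrm{var}(x)/8x^2)$ with
$\mathrm{var}(x) = x(1-x)/N$ is exposed (`correct = TRUE`); it is off by
default because the uncorrected estimator is what the identity checks and
the classical reporting convention assume.

Two filters matter and are applied at different places deliberately:

* **Usability** (`lm_filter()`): loci with band frequency $\ge 1 - 3/N$ are
  excluded from allele-frequency and heterozygosity summaries, where the
  square-root estimator's bias is worst. The rule is evaluated per locus at
  its own non-missing $N$. Percent polymorphism and the Shannon index use
  *all* scored loci — published primer screens count every scored band, and
  entropy needs no allele-frequency estimate. Below $N = 4$ the bound drops
  to $0.25$ and the filter degenerates; it is still applied literally, with
  a warning.
* **Polymorphism**: a locus is polymorphic when its major allele frequency
  is below $0.95$ *or* both phenotypes are observed in scope. The practical
  override is what makes per-population classifications stable at small
  sample sizes; at pooled (species) scope the two rules almost always
  coincide.

Shannon's index is computed per locus as the base-2 phenotype entropy
$-[f\log_2 f + (1-f)\log_2(1-f)]$ (convention $0\log 0 = 0$) and summarised
as the arithmetic mean over loci, so its ceiling is 1 bit for diallelic
phenotypes. Published tables of this statistic sometimes exceed 1 because
they aggregate multi-band primer phenotypes instead; the per-locus mean is
reported here and no attempt is made to reproduce that alternative scale.
Percent-polymorphism percentages are rounded half-up to integers, which is
the convention that reproduces published primer-screen tables cell by cell
(see `scripts/acceptance.R`).

## AMOVA

`squared_distance_matrix()` counts mismatching loci per pair — exactly the
squared Euclidean distance between 0/1 rows, the standard AMOVA choice for
binary data. The two-level partition follows the classical distance
identities
$SSD_{total} = \frac1N\sum_{i<j} d_{ij}$,
$SSD_{within} = \sum_{pops}\frac1{N_p}\sum_{i<j\in p} d_{ij}$,
with $\sigma^2_w = MSD_{within}$,
$\sigma^2_a = (MSD_{among} - MSD_{within})/n_0$,
$n_0 = (N - \sum N_p^2/N)/(k-1)$, and
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)$. A negative among-population
component is reported as computed (`var_among`, `phi_raw`) with `phi_st`
truncated at zero for reporting. Significance permutes whole individuals
across populations; with the default 999 permutations the smallest
attainable p is $1/1000 = 0.001$. All-zero distance matrices return both
components as 0 and $\Phi_{ST}$ as undefined rather than 0/0.

## Similarity and principal coordinates

For symmetric binary characters Gower's general similarity coefficient
reduces to simple matching — shared band *absence* counts as a match. That
choice is pinned and documented because the asymmetric alternative (Jaccard)
changes every downstream number; for anonymous dominant markers the
band-absent state is a real homozygous genotype, not missing information.
Gower's theorem guarantees $d = \sqrt{1-S}$ is Euclidean-embeddable, so
classical scaling (double centering + eigendecomposition, via
`stats::cmdscale`) reconstructs those distances exactly; the test suite
verifies the reconstruction to $10^{-8}$ and checks the eigenvalues against
an independent double-centering eigendecomposition. Percent variance per
axis uses the positive eigenvalues as denominator; negative eigenvalues can
only arise under pairwise-deletion missingness and are reported but carry no
axes. Population-averaged similarity tables exclude self-pairs on the
diagonal and round half-up to integer percent; a singleton population has an
undefined diagonal entry.

## Bayesian admixture clustering

`gibbs_fit()` implements the admixture model for binary band data. Dominant
phenotypes are modelled as *haploid* binary alleles — one observation per
individual per locus — the common pragmatic treatment of RAPD/ISSR data in
STRUCTURE-style analyses. The genotypic recessive-allele model (which
integrates over the hidden heterozygote state) is deliberately out of scope;
the haploid simplification slightly understates uncertainty at intermediate
frequencies but leaves cluster recovery intact, which is what the recovery
experiments measure.

Each sweep draws (i) cluster×locus band frequencies from
Beta(1 + #present, 1 + #absent) over current assignments, (ii) a cluster of
origin for every observation $\propto q_{ik} f_{kl}^x (1-f_{kl})^{1-x}$,
(iii) memberships $q_i \sim$ Dirichlet($\alpha$ + assignment counts), and
(iv) a Metropolis update of $\alpha$ (normal proposal, sd 0.025, uniform
prior on (0, 10), initial 1.0 — the STRUCTURE defaults). The recorded
per-sweep log-likelihood is the mixture form
$\sum_{il}\log\sum_k q_{ik}P(x_{il}\mid f_{kl})$, and
`ln_prob_data()` turns the trace into the penalised-mean evidence estimate
$\overline{\ln L} - \mathrm{var}(\ln L)/2$. Sampled frequencies are clamped
to $[10^{-12}, 1-10^{-12}]$ and memberships floored at $10^{-12}$ so log
terms stay finite; if every Dirichlet gamma draw underflows the membership
row falls back to uniform. The sweep kernel is compiled C++ driven by R's
RNG, so a seed makes runs bit-reproducible.

Model size uses the Evanno statistic over replicate runs:
$\Delta K = |L(K{+}1) - 2L(K) + L(K{-}1)|/\mathrm{sd}(L(K))$, maximised over
interior $K$; zero replicate spread leaves $\Delta K$ undefined at that $K$
(warned and excluded). The default grid is $K = 1$ to the number of
populations plus three, with 5 replicates. Desk-scale defaults are 2,000
burn-in and 5,000 recorded sweeps — on the simulated designs used in the
tests (≈60 individuals × 150 loci) the evidence estimates stabilise well
before that, and the long 100,000/100,000 × 20 field protocol remains
available through the arguments. Labels are not aligned across replicate
runs (CLUMPP-style matching is out of scope); bar-plot data come from a
single run.

## The simulator: what it emulates and what it does not

`simulate_dataset()` generates the study design the analyses expect:
4 populations of (10, 10, 13, 20) individuals scored at 180 RAPD + 49 ISSR
loci by default, with per-locus population frequencies from the
Balding–Nichols model $p_k \sim \mathrm{Beta}(p_0(1-F)/F,\,(1-p_0)(1-F)/F)$
around an ancestral $p_0 \sim U(0.1, 0.9)$. The default $F = 0.5$ matches
the strong differentiation reported for fragmented island tree populations
(combined Φ_ST near 0.54); recovery experiments use $F$ = 0.05–0.4.
Genotypes are Binomial(2, $p_k$) and a band appears iff ≥1 amplified allele
— so observed band frequency collapses to $1-(1-p)^2$, which the tests
check directly. Optional symmetric-Dirichlet admixture draws per-locus
origins; optional uniform missingness masks cells.

The generator deliberately omits several features of real gel data:
linkage between fragments of one primer, scoring error and band
co-migration, size-dependent amplification dropout, and mutation/drift
history beyond the single-F island model. Passing recovery tests therefore
demonstrates correctness of the estimators under the model's own
assumptions, not robustness to gel artefacts. The latent genotypes feed
`true_fst()`, a Weir–Cockerham variance-components estimator
($\sum a/\sum(a+b+c)$ over loci) used as the independent oracle: at
$F = 0.35$ the phenotype-based Φ_ST runs ≈0.07 above it, the expected
dominance bias, and the acceptance checks tolerate ±0.08.

## Numerical choices and test scales

* %P and similarity percentages round half-up (`floor(x + 0.5)`), matching
  the published-table convention; internal statistics are never rounded.
* SSD additivity is asserted to $10^{-9}$ relative; PCO reconstruction to
  $10^{-8}$.
* Permutation p-values use the add-one convention, so p can never be 0.
* Sub-seeds for replicate runs and pipeline stages are drawn from the master
  seed via `sample.int(.Machine$integer.max, ...)`, keeping every stream
  inside 32-bit range and making the whole battery a function of one seed.
* Test and acceptance problem sizes (e.g. 200 null simulations at
  N = 100 × 200 loci with 199 permutations; five ΔK experiments at
  60 × 150 with a K = 1..6 × 5-replicate grid at 2,000/5,000 sweeps) were
  chosen as the smallest designs at which the checked properties are stable
  across seeds.

## Known limitations

* No F_IS or linkage statistics: dominant data cannot support them without
  assumptions beyond HWE.
* Two-level AMOVA only (among/within populations); no regional grouping
  level.
* The cluster model is haploid-binary; allele-frequency correlation between
  clusters and LOCPRIOR-style models are not implemented.
* The similarity variant is fixed to simple matching by default; Jaccard
  users should be aware every downstream table changes.
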