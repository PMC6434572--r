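---
title: "Models and methods behind chimerapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chimerapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimerapop)
```

`chimerapop` analyses microsatellite data from colonial invertebrates in
which two biological realities break the textbook diploid model:
chimerism (fused colonies carrying more than two alleles per locus) and
winter dieback (a seasonal bottleneck between sampling campaigns). This
vignette explains the models implemented, the defaults chosen where the
design space was genuinely open, and what the synthetic-data generator
does and does not emulate.

## 1. The dual scoring model

A raw observation is a set of peaks (fragment size, fluorescence height)
per sample and locus. Two genotype variants are derived from the same
peaks:

* **Diploid** (`call_diploid`): the two tallest peaks; a single peak is
  a homozygote (size repeated — the standard codominant convention); no
  peaks is a missing call. Height ties break toward the smaller
  fragment, which makes calls deterministic across platforms.
* **Polyploid** (`call_polyploid`): all peaks within a height ratio
  (default 0.5) of a reference height, capped at the four tallest — a
  tetraploid ceiling, since a two-colony chimera carries at most four
  alleles per locus.

The reference for "within 50% of the two main peaks" is ambiguous in
principle: it could be the lower, the higher, or the mean of the two
main heights. The package defaults to the **lower** of the two, which is
the most permissive monotone reading (any peak comparable to the weaker
main signal is admitted); the mean is available via
`reference = "mean"`. Because the threshold is anchored at the main
peaks, the diploid call is always a subset of the polyploid call, and
the detected chimera proportion is non-increasing in the ratio — both
are tested properties.

A colony is flagged chimeric when any locus shows three or more distinct
alleles. Note this is a *detection* criterion: a chimera whose partner
genotype shares alleles, or whose secondary tissue contributes weak
signal, is invisible. The generator's truth flags are therefore a
superset of detectable chimeras.

Filtering drops loci with more than 10% missing calls first, then
samples missing more than two of the surviving loci — the order matters
and is fixed; filtering is idempotent.

## 2. Diversity and screening statistics

* Expected heterozygosity uses Nei's small-sample correction
  `T/(T-1) * (1 - sum p^2)` over `T` gene copies.
* The inbreeding coefficient is Weir–Cockerham's within-population *f*
  from variance components summed over loci, not the simple
  `1 - Ho/He` ratio (which is reported alongside). Its permutation test
  shuffles allele copies among individuals within the population, which
  enforces Hardy–Weinberg as the null; the reported p-value is
  two-sided. Standard errors across loci use the `n-1` denominator.
* Rarefied allelic richness is the exact hypergeometric expectation of
  distinct alleles in `2g` gene copies; private allelic richness
  multiplies the focal presence probability by the absence probabilities
  in every other population (a product-form closed expression, exact
  because rarefied subsamples are independent across populations). The
  reference size defaults to `g = 19` individuals and is automatically
  capped at the smallest per-locus sample after filtering.
* Hardy–Weinberg exact tests enumerate all genotype tables conditional
  on allele counts (Levene distribution) up to four alleles. Beyond
  that, a seeded Monte Carlo chain performs random transpositions of
  allele copies between individuals; a uniform walk over copy
  arrangements induces exactly the Levene distribution over tables, so
  moves are always accepted and no Metropolis correction is applied.
  The chain reproduces enumeration p-values within 0.01 on toys (a
  tested property).
* Linkage disequilibrium is a permutation genotypic-association test: a
  G statistic on the two-locus genotype contingency table, with the null
  built by permuting one locus's genotypes among individuals. This
  deliberately differs from EM-based haplotype likelihood-ratio tests,
  which assume Hardy–Weinberg proportions — an assumption visibly
  violated in strongly outcrossing colonial species. One row is emitted
  per population and locus pair, so the family size is always
  `choose(L,2) * P` (420 for 8 loci and 15 populations; 168 for 6).
* Null alleles use the heterozygote-deficit estimator
  `r = (He - Ho)/(He + Ho)` with a bootstrap-over-individuals flag
  (1,000 resamples). A fuller genotyping-error suite (stutter,
  large-allele dropout) is intentionally out of scope.
* Multiple testing uses the Benjamini–Yekutieli style threshold
  `CPV = alpha / H_k` (H_k the k-th harmonic number), reported at three
  decimals for display and at full precision for comparisons.

## 3. Differentiation

Pairwise F_ST is Weir–Cockerham θ with significance by permuting
individuals between the pair; p-values use `(b+1)/(B+1)` and are never
exactly zero. Jost's D_est uses Nei–Chesser sample-size-corrected Hs and
Ht per locus; the multi-locus value averages the `(Ht - Hs)` and
`(1 - Hs)` components across loci before taking the ratio
("averaging components"), which is more stable than averaging per-locus
ratios when single loci are nearly monomorphic. Significance (D > 0)
comes from bootstrapping loci.

AMOVA operates on gene copies (2N haplotypes) at three levels — among
groups, among populations within groups, within populations — with the
0/1 allele distance, per-locus variance components summed across loci,
and the three standard permutation schemes (whole populations among
groups for F_CT; individuals among populations within groups for F_SC;
individuals among all populations for F_ST). The within-individual level
is deliberately excluded: heterozygote excess is F_IS's business, and
folding it into AMOVA would conflate outcrossing with structure.
Confidence intervals bootstrap loci (cheap, because per-locus components
are precomputed). With a single group the design degenerates cleanly:
F_CT is undefined and F_SC = F_ST.

PCoA is classical scaling (Gower double-centering) of linearized
pairwise F_ST, `F_ST/(1 - F_ST)` with negative estimates truncated at 0;
axis signs are fixed by making the largest-magnitude loading positive.
Which genetic distance fed an ordination is recorded in the report.
Likelihood assignment scores each individual's genotype against each
founder's allele frequencies under Hardy–Weinberg, leave-one-out when
the individual belongs to the founder, with unseen alleles given
frequency `1/(2n+2)` — this avoids minus-infinity log-likelihoods
without drowning the signal, and the leave-one-out removes self-bias.
The polyploid variant's F_ST uses equal-dosage allele frequencies (each
individual contributes weight 1 split over its distinct alleles — allele
dosage is unobservable in a chimera) in a Nei-style `(Ht - Hs)/Ht`
partition; without chimeras this reduces exactly to the diploid
frequency partition, a tested identity.

## 4. Connectivity

The dispersal model is a transparent threshold graph: sites are adjacent
when `distance <= velocity * PLD`, with PLD swept over 2/12/24/36 h
(the span of observed larval viability for didemnid ascidians). An
optional pairwise travel-time matrix can replace the scalar model; when
travel times are asymmetric, weak connectivity (either direction) is
used, because cluster partitions are undirected objects. Clusters are
connected components with ids ordered by the smallest member site, so
partitions coarsen monotonically in PLD — a tested invariant. The sweep
raises two situations that block or duplicate cluster-stratified AMOVAs:
every sampled population in its own cluster (AMOVA impossible), and two
PLDs inducing the same partition on the sampled populations (one model
suffices). This threshold abstraction is honest about what it is not: no
hydrodynamic simulation, particle tracking, or GIS raster processing.

## 5. The synthetic-data generator

The generator is first-class, tested code; its defaults encode the study
design the package targets:

| parameter | default | rationale |
|---|---|---|
| site groups / populations | 3 groups of 9/5/1 | a main aquaculture sound, a second sound, one port |
| colonies per population | 30 | standard field sample |
| loci / alleles | 8 loci, 3–13 alleles | consistently amplifying polymorphic panel |
| global frequencies | Dirichlet(0.3) | skewed spectra with rare alleles, He ≈ 0.55–0.70 |
| theta_ct / theta_sc | 0.015 / 0.035 | weak hierarchical structure (F_CT ≈ 0.015, F_SC ≈ 0.035) |
| avoidance | 0.3 | mean F_IS ≈ −0.2 (range ≈ −0.36 to −0.04) |
| chimera_rate / fusion_fraction | 0.35 / 1 | detected chimera proportions of ~17–48% per population |
| dieback_survival | 0.8 | winter samples of 22–28 from 30 |
| drift_strength | 0.03 | a detectable summer-vs-winter F_CT near 0.03 |
| missing_rate | 0.02 | comfortably below the 10% locus filter |
| peak model | lognormal, sdlog 0.25, floor 100 | ~95% replicate concordance at default noise |

Hierarchical frequencies use the Balding–Nichols reparameterisation:
children are Dirichlet with concentration `p (1-theta)/theta`, so each
marginal has mean `p` and variance `p(1-p) theta` and the theta
parameters *are* the expected F-statistics — which makes parameter
recovery exact in expectation and testable (generating theta_sc = 0.05
is recovered by multi-locus θ within ±0.02 at the design size).

The outcrossing excess is a mating-avoidance mechanism: an identical
second allele is redrawn with probability `v`, giving
`E[F_IS] = -v * sum(p^2) / (1 - sum(p^2))`. Chimera partners are drawn
from the same population by default (field sampling is within-site;
cross-population fusion is available but off). Peak heights are
lognormal per allele copy, with secondary-genotype copies scaled by the
fusion fraction and shared-size contributions summed; no stutter is
simulated by default.

The winter model is explicit about its ignorance: dieback is a
per-population subsample of colonies (the bottleneck), after which the
winter sample is either the survivors themselves
(`winter_mode = "survivors"`) or fresh recruits drawn from the
survivors' empirical frequencies perturbed by Balding–Nichols drift
(`winter_mode = "recruits"`, the default). Whether real winter colonies
are survivors or recruits is unknown; both are supported and neither is
asserted.

**What passing tests do and do not show.** The generator emulates the
statistical skeleton of a field study — hierarchical frequencies,
outcrossing, chimerism, dieback, peak noise, missingness. It does not
emulate stutter artifacts, allele-size homoplasy, clonal replicates,
uneven amplification across loci, or spatially autocorrelated sampling
within a site. Green tests therefore certify the *analysis machinery*
and its calibration under the modelled conditions, not the field
behaviour of any particular marker panel.

## 6. Numerical choices and problem sizes

* All permutation/bootstrap p-values are `(b+1)/(B+1)`.
* Height and statistic ties break deterministically (smaller fragment
  first; first founder wins assignment ties).
* Every stochastic routine takes a seed; the pipeline fans one master
  seed into per-stage child streams so stages can be re-run in
  isolation, and a fixed seed reproduces the full report byte for byte.
* The test suite exercises oracle equivalence on small instances
  (≤ 20 individuals, ≤ 10 sites) where brute-force enumeration is
  exact, calibration on 200 simulated datasets of 8 populations × 12
  individuals × 4 loci (F_CT rejection within 2 SE of 5% under random
  grouping), and parameter recovery at the full design size over 20
  seeds. These sizes were chosen as the smallest at which the checked
  distributional properties are informative.
* AMOVA's locus bootstrap defaults to 20,000 replicates and pairwise
  tests to 10,000 permutations at the user surface; the pipeline
  defaults are smaller (999/200) because a 15-population study runs all
  105 pairs.

## 7. Known limitations

* Polyploid allele frequencies assume equal dosage; true dosage in a
  chimera depends on tissue mixture and is unobservable from one
  electropherogram.
* The LD test conditions on single-locus genotype frequencies and so
  has reduced power against associations expressed purely through
  heterozygote phase.
* Jost's D p-values come from locus bootstraps, which are weak with few
  loci (single-locus datasets get point estimates only).
* The connectivity model treats currents as isotropic unless a
  travel-time matrix is supplied.
* AMOVA assumes every individual belongs to exactly one population and
  ignores within-individual structure by design.
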