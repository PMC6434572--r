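# chimerapop

Chimera-aware microsatellite population genetics for colonial invaders.

## The problem

Colonial ascidians such as *Didemnum vexillum* are aggressive biofoulers
whose invasion pathways are usually reconstructed from standard diploid
microsatellite genotypes. Two life-history traits undermine that standard
model:

* **Chimerism** — genetically distinct colonies fuse, so a single tissue
  sample can carry more than two alleles per locus. Scoring only the two
  tallest electropherogram peaks silently discards the second genotype;
  scoring every strong peak turns the data polyploid.
* **Winter dieback** — seasonal colony regression acts as a demographic
  bottleneck between sampling seasons, reshuffling allele frequencies and
  with them every downstream inference about diversity, structure and
  connectivity.

`chimerapop` implements the full analysis chain needed to quantify how
much these two traits move the answers, for population geneticists and
biosecurity analysts working with peak-level microsatellite data from
colonial invertebrates.

## What the package computes

Starting from a raw peak table (sample x locus lists of fragment sizes
with peak heights), the package:

1. **Calls two dataset variants** from the same peaks: a *diploid*
   dataset (the two tallest peaks; one peak scored as a homozygote) and a
   *polyploid* dataset (all peaks within 50% of the height of the lower
   of the two main peaks, capped at four alleles), and flags a colony as
   chimeric when it shows more than two alleles at any locus.
2. **Screens and summarises**: observed/expected heterozygosity (with
   Nei's 2n/(2n−1) correction), multi-locus Weir–Cockerham F_IS with a
   permutation test, rarefied allelic richness and private allelic
   richness at a reference sample size (hypergeometric closed forms),
   exact Hardy–Weinberg tests (full enumeration up to four alleles, a
   seeded Monte Carlo chain beyond), permutation linkage-disequilibrium
   screening, and a null-allele estimator r = (H_E − H_O)/(H_E + H_O)
   with a bootstrap flag. Test families are corrected with the
   Benjamini–Yekutieli threshold **CPV = α / Σᵢ₌₁ᵏ (1/i)**.
3. **Measures differentiation**: pairwise Weir–Cockerham θ and Jost's
   D_est (bootstrapped over loci) with their Pearson cross-check,
   three-level AMOVA (F_CT / F_SC / F_ST with the three standard
   permutation schemes and locus-bootstrap CIs), Mantel isolation by
   distance, PCoA on linearized F_ST, frequency-based likelihood
   assignment to preset founder populations, and a Nei-style equal-dosage
   F_ST for the polyploid variant.
4. **Models dispersal connectivity**: sites are joined when
   `distance ≤ velocity × PLD`, for pelagic larval durations of
   2/12/24/36 h; connected components define dispersal clusters, and
   AMOVA is re-stratified by cluster membership.
5. **Simulates whole studies with known truth**: hierarchical
   Balding–Nichols allele frequencies (θ_CT, θ_SC map directly onto the
   F-statistics), outcrossing excess (negative F_IS), chimeric fusion,
   lognormal peak heights, amplification failure, winter dieback with
   optional drift, and planar site maps — so every stage above is
   testable end to end without any field data.

## Worked example

```r
library(chimerapop)

cfg <- simulation_config(seed = 7)    # the default two-season study design
st  <- simulate_study(cfg)

summer <- st$peaks[st$peaks$season == "summer", ]
dip  <- filter_dataset(call_dataset(summer, "diploid"))
poly <- filter_dataset(call_dataset(summer, "polyploid"))

diversity_table(dip, poly, g = 19, n_perm = 200, seed = 1)
#>    n a_n_dip a_n_poly  a_rn  a_rp   h_o   h_e   f_is    cc   (first rows)
#> 1 30   5.000    5.125 4.767 0.079 0.823 0.684 -0.207 0.333
#> 2 30   4.375    4.625 4.291 0.000 0.819 0.674 -0.219 0.333
#> 3 30   4.750    5.000 4.639 0.000 0.734 0.653 -0.127 0.267
```

Each row is one population: mean alleles per locus under both scoring
rules (the polyploid count is never smaller), richness rarefied to 19
individuals, heterozygosities, the Weir–Cockerham inbreeding coefficient
(negative: heterozygote excess from obligate outcrossing) and the
proportion of chimeric colonies (here 27–43%).

```r
hier <- hierarchy_spec(setNames(st$truth$pop_table$site_group,
                                st$truth$pop_table$population))
amova(dip, hier, n_perm = 499, n_boot_loci = 1000, seed = 2)
#>                            level       F     p percent_variation  ci_low ci_high
#>              Among groups (F_CT) 0.01551 0.002             1.551 0.01071 0.02021
#>  Among pops within groups (F_SC) 0.02339 0.002             2.303 0.01681 0.02939
#>               Within pops (F_ST) 0.03854 0.002            96.146 0.02980 0.04611
```

The generator was run with θ_CT = 0.015 and θ_SC = 0.035; the AMOVA
recovers weak-but-significant hierarchical structure of exactly that
magnitude, with ~96% of the variation within populations — the typical
signature of a well-mixed invasive metapopulation.

The FDR threshold for a family of 420 linkage tests:

```r
fdr_correct_by(p_values, alpha = 0.05)   # k = 420
#> <fdr_family> k = 420, alpha = 0.05, CPV = 0.008 (0.0075544)
```

`run_pipeline(cfg, out_dir = "report")` executes the whole study —
both variants, both seasons, all hierarchies, the PLD sweep, PCoA and
assignment — and writes a CSV report bundle plus a JSON run manifest.
A command-line wrapper lives at `inst/scripts/run_study.R`.

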