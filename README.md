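# dielniche

Quantifying diel activity niches — diurnal, nocturnal, crepuscular,
cathemeral — from long-term behavioural tracking of individually housed
fish, and analysing how those niches evolve across a species radiation.

The package implements the full chain of such a study:

1. **Tracking** — percentile-background subtraction (per-pixel 95th
   percentile over a rolling window), blob detection with a 100 px minimum
   area, interpolation of missing detections, despiking of >200 px
   single-frame jumps, 0.5-s boxcar smoothing, px→mm calibration.
2. **Activity & rest** — speed from subsequent positions; *movement* =
   speed > 15 mm s⁻¹; *rest* = less than 5% movement in a sliding 60-s
   window; midnight-anchored 30-min bins; species daily profiles; total
   rest per day; vertical rest position tests; Fisher g-test periodograms.
3. **Diel classification** — PCA of the z-scored 48-bin species profiles
   (bins as observations, species as features): PC1 loadings measure
   diurnal–nocturnal preference, PC2 loadings crepuscularity. Ward
   clustering at k = 3 plus a variability rule that reassigns species to
   *cathemeral* when their profile range falls below twice the mean
   per-bin SD.
4. **Phylogenetic comparative engine** — Pagel's λ and Blomberg's K (and
   multivariate K), PGLS, simulation-based phylogenetic ANOVA,
   phylogenetically corrected two-block PLS, BM/OU/EB model fitting with
   AICc, OU ancestral states, and Mk models of guild evolution including
   the *bridge-only* variants (no direct diurnal↔nocturnal transitions)
   that formalise the crepuscular-bridge hypothesis.
5. **Allele-frequency GWAS** — GATK-style site filtering (QD/FS/MQ/rank-sum
   clauses, 900–1900 summed-depth window, biallelic placed SNPs, minor
   allele in ≥2 individuals), Hardy–Weinberg posterior allele frequencies
   from genotype likelihoods by EM, paired GLM and PGLS association scans
   over scaled frequencies (2f − 1), and HAV (highly associated variant)
   calling at genome-wide cutoffs.

Seeded synthetic generators produce every input — tracks, frame stacks,
trees, continuous and discrete trait histories, genotype likelihoods with
planted associations — with machine-readable ground truth, so the whole
pipeline is testable end to end without videos or genomes.

## Worked example

Simulate a small cohort (12 species × 4 individuals × 3 days), classify
diel niches, and measure phylogenetic signal:

```r
library(dielniche)

co  <- simulate_cohort(n_species = 12, n_per_species = 4, days = 3,
                       fps = 1, seed = 7)
cls <- classify_diel(co$profiles, co$schedule)
cls$pca
#> diel activity PCA: 12 species, PC1 65.6%, PC2 10.8% of variance

table(truth = as.character(co$guild_truth),
      called = as.character(cls$table$guild))
#>              called
#> truth         crepuscular diurnal nocturnal
#>   cathemeral            3       0         0
#>   crepuscular           1       0         0
#>   diurnal               0       4         0
#>   nocturnal             0       0         4

pc1 <- setNames(cls$table$pc1, cls$table$species)
pagel_lambda(co$tree, pc1)
#> lambda = 0.0000 (p = 1)
blomberg_k(co$tree, pc1, n_perm = 199, seed = 1)
#> K = 0.6200 (p = 0.355)

range(co$total_rest)
#> total rest range: 3.2-8.8 h/day
```

PC1 separates day-active from night-active species (65.6% of profile
variance here) and every diurnal/nocturnal species is recovered. The three
cathemeral species land in the crepuscular cluster because the cathemeral
variability override needs more individuals per species to be informative
(see the methods vignette); at the full study design of ~8 individuals it
fires reliably. λ ≈ 0 and K < 1 say that, on this small simulated cohort,
closely related species do *not* have similar day–night preferences —
the hallmark of temporal niche partitioning. Guild evolution can then be
tested with `fit_mk()` under `"bridge-SYM"` / `"bridge-ARD"` constraints
against `ER`/`SYM`/`ARD`, compared with `compare_aic()`.

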