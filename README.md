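# paleokin

Desk-scale tools for two questions that meet in the study of ancient
perinatal burials: **who was related to whom**, from low-coverage
pseudo-haploid ancient-DNA genotypes, and **who survived birth and for how
long**, from the barium chemistry of deciduous tooth enamel.

## Who it is for

Ancient-DNA and bioarchaeology analysts who want a small, fully tested,
reproducible implementation of the standard statistics — not a wrapper
around external binaries — plus a simulator that provides exact ground
truth for validating them.

## What it computes

**Genetics** (EIGENSTRAT ASCII geno/snp/ind in, TSV out):

* *Outgroup-f3*, `f3(O; A, B) = E[(o−a)(o−b)]`: shared drift of A and B
  relative to an outgroup, for ranking genetic affinity.
* *f4*, `f4(A, B; C, D) = E[(a−b)(c−d)]`: four-population symmetry test;
  deviation from 0 means differential allele sharing. Both come with
  weighted block-jackknife SEs, Z-scores, a |Z| ≥ 3 significance flag and a
  10,000-SNP validity rule.
* *Mismatch-rate kinship*: the pairwise SNP mismatch rate is interpolated
  between the unrelated baseline (r = 0) and the identical endpoint
  (r = 1, with m_identical = m_unrelated/2 under pseudo-haploidy), then
  classified into degrees by the expected genome-sharing fractions
  1, 1/2, 1/4, 1/8, 1/16, 0 (identical twin → 4th degree → unrelated).
* *Genetic sexing* from the Y fraction of X+Y aligned reads.
* A *pedigree gene-dropping simulator* (Poisson recombination, tracked
  haplotype ancestry, pseudo-haploid sampling with missingness / error /
  contamination) providing exact realized-IBD ground truth.

**Tooth chemometrics** (LA-ICP-MS line-scan cps series in):

* Gas-blank subtraction, LOD = 3× blank SD censoring, Ca-normalised
  isotope ratios, georeferencing along the ablation line.
* Per-ROI percentile tables (point-in-polygon, boxplot-ready).
* Post-neonatal-line enamel layer thickness from the "prenatal mean + 3 SD"
  threshold, in µm with the spot size as uncertainty — the breastfeeding
  biomarker used to separate stillbirth from short survival.
* One-point Ba calibration (NIST SRM 1486, 281 µg/g), crown-formation
  timing from prism lengths, collagen C:N QC (2.9–3.6 window), a
  surface-contamination (Al/Ca) screen, and a phantom scan generator.

## Worked example

Simulate a twin pair, a first-cousin pair and three unrelated pairs at
50,000 SNPs with 15% missingness, then run the kinship analysis:

```r
library(paleokin)
panel  <- simulate_founders(founder_model(50000, seed = 42))
smodel <- sampling_model(missing_rate = 0.15)
parts <- list(simulate_pair_panel("twin",         panel, 1, smodel, seed = 1),
              simulate_pair_panel("first_cousin", panel, 1, smodel, seed = 2),
              simulate_pair_panel("unrelated",    panel, 3, smodel, seed = 3))
calls <- do.call(cbind, lapply(parts, function(p) p$matrix$calls))
ind   <- do.call(rbind, lapply(parts, function(p) p$matrix$ind))
gm    <- genotype_matrix(calls, parts[[1]]$matrix$snp, ind, ploidy = "pseudohaploid")

res <- kinship_analysis(gm,
  pairs = rbind(c("twin_1_a", "twin_1_b"),
                c("first_cousin_1_a", "first_cousin_1_b")),
  unrelated_pairs = rbind(c("unrelated_1_a", "unrelated_1_b"),
                          c("unrelated_2_a", "unrelated_2_b"),
                          c("unrelated_3_a", "unrelated_3_b")))
res[, c("sample_a", "sample_b", "n_overlap", "mismatch_rate", "r", "degree")]
```

```
          sample_a         sample_b n_overlap mismatch_rate     r     degree
1         twin_1_a         twin_1_b     36044         0.184 0.992  identical
2 first_cousin_1_a first_cousin_1_b     36252         0.342 0.132      third
```

The twin pair's mismatch rate (0.184) sits at the identical endpoint — half
the unrelated baseline (m_unrelated 0.366, m_identical 0.183) — giving
r ≈ 1; the cousin pair lands near 1/8 of the way (r = 0.132, 95% CI
0.072–0.191) and is classified third degree. An f4 symmetry test between
the twins is null, as it must be for two samples of the same genome:

```r
compute_f4(gm, "twin_1_a", "twin_1_b", "unrelated_1_a", "unrelated_2_a")
#> f4(twin_1_a, twin_1_b, unrelated_1_a, unrelated_2_a) = -3.83892e-05  SE 0.00189  Z -0.020  [26049 SNPs, 22 blocks]

sex_from_counts(n_x_reads = 4216, n_y_reads = 361)
#> r_y = 0.07887 (X 4216, Y 361) -> XY
```

On the toothchem side, a 5%-noise phantom with a 100 µm postnatal band is
reduced, georeferenced and measured back:

```r
sc    <- synth_scan(noise_sd = 0.05, seed = 7)   # dentin/pre-NNL/post-NNL phantom
bands <- attr(sc, "bands")
g     <- georeference_scan(reduce_scan(sc), ratios = "138Ba/43Ca")
pre   <- g[["138Ba/43Ca"]][bands$from[2]:bands$to[2]]
layer_thickness(g[["138Ba/43Ca"]][bands$from[2]:nrow(g)],
                mean(pre), sd(pre), dwell_time_s = 0.25, scan_speed_um_s = 40)
#> layer thickness: 100.0 +/- 20 um (10 points above 0.3734)
```

Ten surface-adjacent points exceed the maximum-prenatal-ratio threshold
(prenatal mean + 3 SD = 0.3734); at 0.25 s × 40 µm/s = 10 µm per point that
is a 100 µm postnatal layer, recovered exactly, with the 20 µm spot size as
uncertainty.

End-to-end, seed-deterministic runs with JSON configs and manifests:
`run_genetics(config, out_dir)` and `run_toothchem(config, out_dir)`.

## Vignette

`vignettes/methods.Rmd` documents the models and assumptions, every
numerical convention (jackknife form, percentile interpolation, LOD
censoring, thickness contiguity rule, the identical-endpoint halving), what
the simulators do and do not emulate, and known limitations.
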