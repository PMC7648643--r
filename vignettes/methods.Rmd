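---
title: "Methods: pseudo-haploid kinship statistics and enamel chemometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-haploid kinship statistics and enamel chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`paleokin` is a desk-scale toolkit for two analysis chains that are routinely
combined in bioarchaeological studies of perinatal remains: (i) kinship and
drift-sharing statistics on low-coverage, pseudo-haploid ancient-DNA
genotypes, and (ii) LA-ICP-MS elemental imaging of deciduous tooth enamel,
where the barium-to-calcium ratio across the neonatal line acts as a
breastfeeding biomarker. This vignette documents the models, parameter
choices and numerical conventions. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## 1. The genetic data model

Genotypes live in a `genotype_matrix`: an integer matrix of alt-allele
counts (0/1/2, with 9 for missing), one row per SNP, one column per sample,
plus SNP and sample metadata, read and written as ASCII EIGENSTRAT
geno/snp/ind triplets. Pseudo-haploid samples — the standard representation
when coverage is too low to call diploid genotypes, obtained by sampling a
single sequencing read per site — carry only codes 0, 2 and 9, and the
constructor rejects a heterozygous code in a pseudo-haploid column. Packed
binary geno files are deliberately unsupported: fixtures stay
human-inspectable. Coordinates are 1-based and must increase strictly
within a chromosome; chromosome tokens are normalised to `{1..22, X, Y,
MT}` (EIGENSTRAT's numeric 23/24/90 are accepted on input).

## 2. The synthetic world

The simulator is a stated world, not a tuning dial. Its defaults are fixed
once and the tests inherit them.

**Founders.** Per-SNP alt-allele frequencies are drawn from a configurable
law, by default uniform(0.05, 0.95) — a crude stand-in for an ascertained
capture panel, chosen because mismatch-rate kinship only depends on the
aggregate heterozygosity, not on the frequency spectrum's shape. Founder
haplotypes carry independent Bernoulli(p) alleles (Hardy–Weinberg, linkage
equilibrium across SNPs).

**Recombination and pedigrees.** Gene-dropping uses a Poisson crossover
process without interference on a sex-averaged map, by default 22 autosomes
of 1.5 Morgan each with equal SNP counts. This is the simplest model that
delivers the correct expected identity-by-descent (IBD) sharing and a
realistic between-replicate variance for desk-scale panels. Each pedigree
template (`twin`, `parent_offspring`, `full_sib`, `half_sib`, `avuncular`,
`first_cousin`, `first_cousin_once_removed`, `second_cousin`, `unrelated`)
is built explicitly from fresh founders and the realized IBD share is
computed from tracked haplotype ancestry — it is exact ground truth, not an
estimate. Degree bindings follow the unilineal convention: 1st degree =
parent/offspring, 2nd = avuncular, 3rd = first cousins, 4th = first cousins
once removed. Second cousins (expected share 1/32) are provided but sit
outside the 0–4 degree bins.

**Pseudo-haploid sampling.** Per site: with probability `missing_rate` emit
9; otherwise sample one of the two alleles uniformly; with probability
`contamination_rate` replace it by a draw from contaminant frequencies; with
probability `error_rate` flip it. Post-mortem deamination damage is folded
into the symmetric error flip because every downstream statistic here is
allele-symmetric; a strand-aware C→T model would change nothing the package
measures. Missingness is i.i.d. per SNP — real capture data have clustered
coverage, so a green test establishes correctness of the estimators under
the stated model, not robustness to coverage structure.

**What the generator does not emulate:** population structure between
clusters, coalescent ancestry of the founders, linked selection,
reference bias, and sequence-level read artefacts.

## 3. f-statistics

`compute_outgroup_f3(O; A, B)` is the mean over usable SNPs of
$(o-a)(o-b)$ and `compute_f4(A,B;C,D)` the mean of $(a-b)(c-d)$, with $o,
a, b, c, d$ alt-allele frequencies. A SNP is usable when every population
in the statistic has at least one covered sample (listwise deletion over
exactly those populations). Frequencies from a single pseudo-haploid
individual are the sampled 0/1 frequencies, and **no small-sample or
heterozygosity bias correction is applied anywhere**. This differs from
tools that apply such corrections; it is the appropriate convention when
outgroup-f3 is used only as a relative drift-sharing measure ranked across
test individuals, which is the use case this package reproduces. Absolute
f3 levels from this package should not be compared against
bias-corrected published values.

Standard errors come from the weighted delete-one block jackknife (weights
proportional to block SNP counts, the Busing-style form used by the
ADMIXTOOLS family); with equal blocks it reduces to the familiar
$(B-1)/B \sum_j (\theta_{(j)} - \bar\theta)^2$. Blocks default to one per
chromosome; `fixed_snp_count` blocks exist for toy single-chromosome data.
A zero-count block is dropped with a warning; fewer than two non-empty
blocks is an error. Z-scores use the conventional $|Z| \ge 3$ significance
flag, and results from fewer than 10,000 SNPs are emitted but flagged
invalid rather than silently dropped — both thresholds configurable.

## 4. Mismatch-rate kinship

For a pair of pseudo-haploid samples the mismatch rate is the fraction of
jointly covered SNPs with different calls; its SE comes from the same block
jackknife. Under Hardy–Weinberg founders the expectations are

* unrelated pair: $\sum_j 2 p_j (1-p_j) / L$,
* identical pair (same genome sampled twice): $\sum_j p_j (1-p_j) / L$,

so the identical endpoint is **half** the unrelated rate. The relatedness
coefficient interpolates linearly:
$r = (m_{un} - m_{pair}) / (m_{un} - m_{id})$, with $m_{id} = m_{un}/2$ by
default. This halving convention is a deliberate design choice: the
alternative reading of the identical endpoint as literally "zero mismatch"
would compress all related pairs toward the unrelated end and no longer map
third/fourth-degree pairs onto 1/8–1/16 of the interval. An observed
same-individual or twin rate can override the default
(`observed_identical`), which is the preferred anchor when one is
available. The pair-rate CI is propagated to r at first order with the
baselines treated as fixed constants — appropriate when the baseline comes
from a much higher-coverage individual; the residual baseline error biases
all pairs coherently rather than adding pair-level noise.

Degree classification uses arithmetic midpoints between the expected shares
{1, 1/2, 1/4, 1/8, 1/16, 0} (boundaries 0.75, 0.375, 0.1875, 0.09375,
0.03125); a tie at a boundary goes to the more-related class. By default
the point estimate is classified; `ci_rule = "within_bin"` instead returns
`indeterminate` whenever the 95% CI spans a boundary. QC failure (overlap
below `min_snps`, default 10,000) always yields `indeterminate`.

A useful first-order property, verified by simulation in the test suite:
i.i.d. symmetric call error inflates all mismatch rates but cancels in r
when the baselines are estimated from equally noisy pairs.

Genetic sex is called from the Y fraction of sex-chromosome reads,
$r_y = n_Y/(n_X+n_Y)$: XY at $r_y \ge 0.075$, XX at $r_y \le 0.016$,
indeterminate between. The thresholds follow common ancient-DNA sexing
practice, since the source analyses report only the qualitative call.

## 5. Enamel chemometrics

**Reduction.** Per ablation line, the gas-blank window (default 62 points,
a ~10 s blank) gives each isotope's blank mean and SD; the limit of
detection is 3× the blank SD. The blank mean is subtracted, negatives are
clamped to zero, and any corrected value below the LOD is set to zero.
Zeroed values are censoring artefacts, not measurements: a ratio whose
denominator was zeroed is undefined and is **excluded** from all statistics
rather than treated as 0 — setting them to zero would drag ROI means and
percentiles toward zero in low-signal regions.

**Georeferencing.** The n sample points of a line are placed at equal
spacing along the digitised start→end segment (both endpoints included,
n−1 intervals), mirroring how line scans are registered onto histological
images.

**ROI statistics.** Points are assigned to regions of interest by an
even-odd point-in-polygon test with boundary points counted inside (no
geometry package with point-in-polygon is available in the target R stack,
so the primitive is implemented and property-tested here). ROIs may overlap
— stress-line sub-regions subdivide their parent enamel regions, and a
point may legitimately contribute to both. Percentiles (5/25/50/75/95) use
linear interpolation between order statistics (R's type-7 quantile); the SD
uses the n−1 denominator. These conventions are stated because the
exported tables depend on them.

**Layer thickness.** The post-neonatal-line layer boundary uses the
"maximum prenatal ratio" threshold: prenatal mean + 3×SD from the enamel
adjacent to the dentinoenamel junction. The count of supra-threshold enamel
points is converted to distance via integration time × scan speed, with the
laser spot size (default 20 µm) as the reported uncertainty. The supra
run is required to be **contiguous and surface-adjacent**: the source
protocol counts "points above the threshold" without stating contiguity,
but an interior isolated spike is not a surface layer, so contiguity is
enforced here (an undefined ratio terminates the run). Scans crossing the
surface at an angle measure an oblique thickness; no cosine correction is
applied, matching the input geometry convention that thickness is assessed
along the scan.

**Calibration and QC.** Ba mass fractions come from a one-point calibration
against a reference material measured under identical conditions (default:
NIST SRM 1486 bone meal, in-house Ba value 281 µg/g); the transform is
exactly linear. Collagen preservation is screened by the atomic C:N ratio
$(C\%/12.011)/(N\%/14.007)$ with the accepted 2.9–3.6 window. Surface
contamination is screened by comparing the Al/Ca mean in the outermost
10–20 µm against the interior; the screen only annotates, never alters
data.

**Phantom generator.** `synth_scan()` renders a piecewise-constant Ba/Ca
band profile (default dentin 150 µm at ratio 1.0, prenatal enamel 200 µm at
0.3, postnatal enamel 100 µm at 0.6 — a +100% step, comfortably above the
>30% increase expected of a breastfeeding signal) on top of an additive
gas-blank background, with multiplicative Gaussian noise (default relative
SD 5%) as a pragmatic stand-in for Poisson counting noise at high count
rates. With zero noise the reduced ratios equal the band levels exactly,
which pins down the whole reduction chain. The phantom does not emulate
curved incremental geometry, diffusion-blurred band edges, or
heteroscedastic low-count channels; thickness-recovery results on phantoms
therefore validate the point-counting logic, not edge-detection on real
gradients.

## 6. Determinism and numerics

All randomness flows from one integer seed per run; substream seeds are
derived deterministically (and kept below 2^31). Pipeline drivers
(`run_genetics`, `run_toothchem`) write byte-identical outputs across
re-runs at a fixed seed and a JSON manifest carrying the resolved
configuration. Configs are JSON. Degenerate inputs fail loudly: empty
statistics, single jackknife blocks, zero-denominator calibrations,
self-intersecting ROI polygons and degenerate scan geometry are all errors,
not warnings.

## 7. Known limitations

* Mismatch-rate kinship assumes both samples are drawn from the same
  (unstructured) population as the baseline pairs; cross-cluster baselines
  would inflate $m_{un}$ and bias r upward.
* No likelihood-based kinship (lcMLkin/KIN-style), IBD segment inference,
  or contamination-aware mismatch correction.
* The f-statistics are uncorrected (see §3) and intended for relative
  comparisons within one dataset.
* The crown-formation regression ships no coefficients: they must come from
  the growth-curve literature via configuration, and the default composition
  rule applies the regression to cumulative prism length (per-segment values
  by differencing), the reading under which concatenating segments is
  consistent; a per-segment rule is available.
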