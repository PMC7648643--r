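# Outgroup-f3 and f4 drift-sharing statistics on pseudo-haploid individuals,
# with weighted delete-one block-jackknife standard errors.
#
# Conventions: allele "frequencies" of a single pseudo-haploid individual are
# the 0/1 sampled-allele frequencies; no heterozygosity / small-sample bias
# correction is applied anywhere. This matches the comparative use of
# outgroup-f3 as a relative drift-sharing measure and differs from tools
# that apply the correction (documented in the methods vignette).

#' Assign SNPs to jackknife blocks
#'
#' @param x a [genotype_matrix()].
#' @param scheme `"per_chromosome"` (default: one block per chromosome, the
#'   natural unit for linkage-robust resampling) or `"fixed_snp_count"`
#'   (contiguous blocks of `n` SNPs, useful for toy single-chromosome data).
#' @param n block size for `fixed_snp_count`.
#' @return integer vector, one contiguous non-negative block id per SNP.
#' @export
make_blocks <- function(x, scheme = c("per_chromosome", "fixed_snp_count"),
                        n = 5000L) {
  scheme <- match.arg(scheme)
  L <- n_snps(x)
  if (scheme == "per_chromosome") {
    as.integer(factor(x$snp$chrom, levels = unique(x$snp$chrom)))
  } else {
    stopifnot(n >= 1)
    as.integer((seq_len(L) - 1L) %/% as.integer(n) + 1L)
  }
}

#' Weighted delete-one block jackknife for a ratio-of-sums estimator
#'
#' The estimator is `sum(sums) / sum(counts)`; blocks are deleted one at a
#' time and the weighted jackknife (weights proportional to block counts;
#' Busing et al. 1999, the form used by the ADMIXTOOLS family) gives the
#' standard error. With `B` equal-count blocks this reduces to
#' `SE^2 = (B-1)/B * sum((theta_(j) - mean(theta_(j)))^2)`.
#'
#' @param sums per-block sums of the per-SNP quantity.
#' @param counts per-block SNP counts (weights).
#' @return list with `estimate`, `std_error`, `n_blocks` (non-empty blocks
#'   used).
#' @export
block_jackknife <- function(sums, counts) {
  stopifnot(length(sums) == length(counts))
  if (any(counts == 0)) {
    warning(sum(counts == 0), " zero-count block(s) dropped from jackknife")
    sums <- sums[counts > 0]
    counts <- counts[counts > 0]
  }
  B <- length(counts)
  if (B < 2) stop("block jackknife needs at least 2 non-empty blocks",
                  call. = FALSE)
  n <- sum(counts)
  est <- sum(sums) / n
  theta_j <- (sum(sums) - sums) / (n - counts)
  h <- n / counts
  theta_jack <- B * est - sum((1 - counts / n) * theta_j)
  tau <- h * est - (h - 1) * theta_j
  var_est <- sum((tau - theta_jack)^2 / (h - 1)) / B
  list(estimate = est, std_error = sqrt(max(var_est, 0)), n_blocks = B)
}

# alt-allele frequency of a population (one or more sample ids) at every SNP;
# NA where no sample in the population is covered
pop_freqs <- function(x, pop) {
  cols <- vapply(pop, function(s) sample_column(x, s), integer(1))
  sub <- x$calls[, cols, drop = FALSE]
  obs <- sub != 9L
  alt <- rowSums(sub * obs)
  tot <- 2 * rowSums(obs)
  ifelse(tot > 0, alt / tot, NA_real_)
}

fstat_result <- function(kind, populations, jack, n_snps_used, min_snps,
                         z_threshold = 3) {
  z <- if (jack$std_error > 0) jack$estimate / jack$std_error else NA_real_
  structure(list(
    statistic_kind = kind,
    populations = populations,
    estimate = jack$estimate,
    std_error = jack$std_error,
    z_score = z,
    n_snps_used = n_snps_used,
    n_blocks = jack$n_blocks,
    significant = isTRUE(abs(z) >= z_threshold),
    valid = n_snps_used >= min_snps
  ), class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  Z %.3f  [%d SNPs, %d blocks]%s\n",
              x$statistic_kind, paste(x$populations, collapse = ", "),
              x$estimate, x$std_error,
              ifelse(is.na(x$z_score), NA, x$z_score),
              x$n_snps_used, x$n_blocks,
              if (!x$valid) "  (below min_snps; not considered)" else ""))
  invisible(x)
}

#' @export
as.data.frame.fstat_result <- function(x, ...) {
  data.frame(kind = x$statistic_kind,
             pops = paste(x$populations, collapse = ";"),
             estimate = x$estimate, std_error = x$std_error,
             z_score = x$z_score, n_snps = x$n_snps_used,
             n_blocks = x$n_blocks, significant = x$significant,
             valid = x$valid, stringsAsFactors = FALSE)
}

check_fstat_inputs <- function(pops) {
  keys <- vapply(pops, function(p) paste(sort(p), collapse = ","),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("the same population appears twice in the statistic", call. = FALSE)
  }
}

fstat_core <- function(x, pops, per_snp_fun, kind, blocks, min_snps,
                       z_threshold) {
  check_fstat_inputs(pops)
  if (is.null(blocks)) blocks <- make_blocks(x)
  stopifnot(length(blocks) == n_snps(x))
  freqs <- lapply(pops, function(p) pop_freqs(x, p))
  usable <- Reduce(`&`, lapply(freqs, function(f) !is.na(f)))
  nu <- sum(usable)
  if (nu == 0) stop("no usable SNPs: every site is missing in at least one ",
                    "population of the statistic", call. = FALSE)
  term <- per_snp_fun(freqs)[usable]
  bl <- blocks[usable]
  sums <- as.numeric(tapply(term, bl, sum))
  counts <- as.numeric(tapply(term, bl, length))
  jack <- block_jackknife(sums, counts)
  labs <- vapply(pops, function(p) paste(p, collapse = "+"), character(1))
  fstat_result(kind, labs, jack, nu, min_snps, z_threshold)
}

#' Outgroup-f3 statistic
#'
#' `f3(O; A, B)` estimated as the mean over usable SNPs (all three
#' populations covered) of `(o - a)(o - b)`, where `o, a, b` are
#' alternative-allele frequencies. Measures the shared genetic drift of A
#' and B relative to the outgroup O: larger values mean more shared
#' ancestry. Standard error and Z-score come from the weighted delete-one
#' block jackknife. Results using fewer than `min_snps` SNPs are reported
#' but flagged `valid = FALSE`, mirroring the usual practice of not
#' considering tests below 10,000 SNPs.
#'
#' @param x a [genotype_matrix()].
#' @param outgroup,a,b population specifications: a sample id or character
#'   vector of sample ids pooled into one population.
#' @param blocks integer block ids per SNP (default [make_blocks()] per
#'   chromosome).
#' @param min_snps validity threshold on the number of SNPs used.
#' @param z_threshold |Z| cut-off for the `significant` flag.
#' @return an `fstat_result`.
#' @export
compute_outgroup_f3 <- function(x, outgroup, a, b, blocks = NULL,
                                min_snps = 10000L, z_threshold = 3) {
  fstat_core(x, list(outgroup, a, b),
             function(f) (f[[1]] - f[[2]]) * (f[[1]] - f[[3]]),
             "outgroup_f3", blocks, min_snps, z_threshold)
}

#' f4 statistic
#'
#' `f4(A, B; C, D)` estimated as the mean over usable SNPs of
#' `(a - b)(c - d)`. Under treeness (A,B) vs (C,D) its expectation is zero;
#' a significant deviation indicates differential allele sharing. Exactly
#' antisymmetric under swapping A,B or C,D.
#'
#' @inheritParams compute_outgroup_f3
#' @param a,b,c,d population specifications.
#' @return an `fstat_result`.
#' @export
compute_f4 <- function(x, a, b, c, d, blocks = NULL, min_snps = 10000L,
                       z_threshold = 3) {
  fstat_core(x, list(a, b, c, d),
             function(f) (f[[1]] - f[[2]]) * (f[[3]] - f[[4]]),
             "f4", blocks, min_snps, z_threshold)
}
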