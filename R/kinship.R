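# Pairwise mismatch-rate kinship for pseudo-haploid data, relatedness
# coefficient by linear interpolation between the unrelated and identical
# endpoints, degree-of-relatedness classification, and read-count sexing.
#
# The identical endpoint defaults to half the unrelated mismatch rate: for
# pseudo-haploid calls under Hardy-Weinberg founders the expected mismatch
# rate of an identical pair is sum p(1-p)/L while an unrelated pair gives
# sum 2p(1-p)/L. Only with this endpoint does a third/fourth-degree pair
# land "1/8 to 1/16 of the way" between the unrelated rate and the
# identical rate. An observed identical-pair rate can override the default.

DEGREE_SHARES <- c(identical = 1, first = 1 / 2, second = 1 / 4,
                   third = 1 / 8, fourth = 1 / 16, unrelated = 0)

#' Pairwise SNP mismatch rate
#'
#' Fraction of jointly covered SNPs at which two samples carry different
#' calls, with a weighted block-jackknife standard error and a 95% CI
#' truncated to [0, 1]. Diploid samples are pseudo-haploidised once (with
#' `seed`) before comparison so that all pairs live on the same
#' pseudo-haploid scale and the analytic identical = unrelated/2 relation
#' stays valid.
#'
#' @param x a [genotype_matrix()].
#' @param a,b sample ids.
#' @param blocks integer block ids per SNP; default per-chromosome.
#' @param min_snps QC threshold on the overlap count.
#' @param seed seed for the (deterministic) pseudo-haploidisation of any
#'   diploid member of the pair.
#' @return object of class `mismatch_result`: `pair`, `n_overlap`,
#'   `n_mismatch`, `rate`, `std_error`, `ci95`, `qc_pass`.
#' @export
pairwise_mismatch <- function(x, a, b, blocks = NULL, min_snps = 10000L,
                              seed = 1L) {
  ca <- x$calls[, sample_column(x, a)]
  cb <- x$calls[, sample_column(x, b)]
  if (x$ploidy[[a]] == "diploid") {
    ca <- pseudo_haploidize(ca, sampling_model(), seed = substream_seed(seed, 11))
  }
  if (x$ploidy[[b]] == "diploid") {
    cb <- pseudo_haploidize(cb, sampling_model(), seed = substream_seed(seed, 13))
  }
  if (is.null(blocks)) blocks <- make_blocks(x)
  mismatch_from_calls(ca, cb, blocks, pair = c(a, b), min_snps = min_snps)
}

#' Mismatch rate from two call vectors
#'
#' Lower-level worker behind [pairwise_mismatch()], convenient when call
#' vectors come straight from the simulator.
#'
#' @param calls_a,calls_b integer call vectors (codes 0/2/9).
#' @param blocks integer block ids per SNP.
#' @param pair optional pair labels.
#' @param min_snps QC threshold on the overlap count.
#' @return a `mismatch_result`.
#' @export
mismatch_from_calls <- function(calls_a, calls_b, blocks,
                                pair = c("a", "b"), min_snps = 10000L) {
  stopifnot(length(calls_a) == length(calls_b),
            length(blocks) == length(calls_a))
  ov <- calls_a != 9L & calls_b != 9L
  n_overlap <- sum(ov)
  if (n_overlap == 0) stop("no overlapping SNPs between ", pair[1], " and ",
                           pair[2], call. = FALSE)
  mm <- as.numeric(calls_a[ov] != calls_b[ov])
  bl <- blocks[ov]
  sums <- as.numeric(tapply(mm, bl, sum))
  counts <- as.numeric(tapply(mm, bl, length))
  if (length(counts) >= 2) {
    jack <- block_jackknife(sums, counts)
    se <- jack$std_error
    nb <- jack$n_blocks
  } else {
    # single-block toy data: binomial SE fallback
    se <- sqrt(sum(sums) / n_overlap * (1 - sum(sums) / n_overlap) / n_overlap)
    nb <- 1L
  }
  rate <- sum(sums) / n_overlap
  ci <- c(max(0, rate - 1.96 * se), min(1, rate + 1.96 * se))
  structure(list(pair = pair, n_overlap = n_overlap,
                 n_mismatch = as.integer(sum(sums)), rate = rate,
                 std_error = se, ci95 = ci, n_blocks = nb,
                 qc_pass = n_overlap >= min_snps),
            class = "mismatch_result")
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat(sprintf("mismatch %s vs %s: %.5f (%d/%d SNPs), 95%% CI [%.5f, %.5f]%s\n",
              x$pair[1], x$pair[2], x$rate, x$n_mismatch, x$n_overlap,
              x$ci95[1], x$ci95[2],
              if (!x$qc_pass) "  (below min_snps)" else ""))
  invisible(x)
}

#' Baseline mismatch rates for the relatedness scale
#'
#' The unrelated baseline is the overlap-weighted mean of the mismatch
#' rates of the supplied unrelated pairs (in the original study: pairs
#' against a high-coverage out-of-site individual). The identical baseline
#' defaults to half the unrelated rate (analytic pseudo-haploid expectation
#' under Hardy-Weinberg); supply `observed_identical` to override it with
#' an observed same-individual or twin rate.
#'
#' @param x a [genotype_matrix()].
#' @param unrelated_pairs two-column matrix / data.frame of sample-id pairs.
#' @param observed_identical optional observed identical-pair rate.
#' @param blocks,min_snps,seed passed to [pairwise_mismatch()].
#' @return list with `m_unrelated`, `m_identical`, and `pairs` (per-pair
#'   mismatch details).
#' @export
estimate_baselines <- function(x, unrelated_pairs, observed_identical = NULL,
                               blocks = NULL, min_snps = 10000L, seed = 1L) {
  up <- as.matrix(unrelated_pairs)
  if (nrow(up) < 1) stop("need at least one unrelated pair", call. = FALSE)
  res <- lapply(seq_len(nrow(up)), function(i) {
    pairwise_mismatch(x, up[i, 1], up[i, 2], blocks = blocks,
                      min_snps = min_snps, seed = seed)
  })
  rates <- vapply(res, `[[`, numeric(1), "rate")
  w <- vapply(res, `[[`, numeric(1), "n_overlap")
  m_un <- sum(rates * w) / sum(w)
  m_id <- if (is.null(observed_identical)) m_un / 2 else observed_identical
  if (m_un <= m_id) {
    stop("degenerate baselines: unrelated rate must exceed identical rate",
         call. = FALSE)
  }
  list(m_unrelated = m_un, m_identical = m_id, pairs = res)
}

#' Relatedness coefficient from mismatch rates
#'
#' Linear interpolation of a pair's mismatch rate between the unrelated
#' (r = 0) and identical (r = 1) endpoints:
#' `r = (m_unrelated - m_pair) / (m_unrelated - m_identical)`.
#' On this scale the expected values are 1 (identical twins), 1/2 (first
#' degree), 1/4, 1/8, 1/16, 0. The CI is first-order propagation of the
#' pair-rate CI, with the baselines treated as fixed constants (in the
#' motivating study they come from a far higher-coverage individual).
#' `r` may fall outside [0, 1] and is reported unclipped.
#'
#' @param m_pair pair mismatch rate, or a `mismatch_result`.
#' @param m_unrelated,m_identical baseline rates (`m_unrelated` >
#'   `m_identical`).
#' @param se_pair optional standard error of `m_pair` (taken from the
#'   `mismatch_result` if one is supplied).
#' @return list with `r`, `se`, `ci95`.
#' @export
relatedness_coefficient <- function(m_pair, m_unrelated,
                                    m_identical = m_unrelated / 2,
                                    se_pair = NULL) {
  if (inherits(m_pair, "mismatch_result")) {
    se_pair <- m_pair$std_error
    m_pair <- m_pair$rate
  }
  if (!(m_unrelated > m_identical) || m_identical < 0) {
    stop("degenerate baselines: need m_unrelated > m_identical >= 0",
         call. = FALSE)
  }
  denom <- m_unrelated - m_identical
  r <- (m_unrelated - m_pair) / denom
  se <- if (is.null(se_pair)) NA_real_ else se_pair / denom
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else c(r - 1.96 * se, r + 1.96 * se)
  list(r = r, se = se, ci95 = ci)
}

#' Classify a relatedness coefficient into a degree of relatedness
#'
#' Point classification by arithmetic midpoints between the expected shares
#' `{1, 1/2, 1/4, 1/8, 1/16, 0}`: boundaries 0.75, 0.375, 0.1875, 0.09375,
#' 0.03125, with a boundary tie going to the more-related class. The label
#' is `indeterminate` when QC failed, or — under `ci_rule = "within_bin"` —
#' when the 95% CI spans a class boundary.
#'
#' @param r relatedness coefficient.
#' @param r_ci95 optional length-2 CI for `r`.
#' @param qc_pass logical QC flag (e.g. overlap >= min_snps).
#' @param ci_rule `"point"` (default: classify the point estimate) or
#'   `"within_bin"` (indeterminate unless the whole CI sits in one bin).
#' @return object of class `relatedness_call` with fields `r`, `r_ci95`,
#'   `degree_label`, `qc_pass`.
#' @export
classify_degree <- function(r, r_ci95 = NULL, qc_pass = TRUE,
                            ci_rule = c("point", "within_bin")) {
  ci_rule <- match.arg(ci_rule)
  labels <- names(DEGREE_SHARES)
  shares <- unname(DEGREE_SHARES)
  bounds <- (shares[-length(shares)] + shares[-1]) / 2
  bin_of <- function(v) {
    # ties at a boundary go to the lower index = more related degree
    labels[sum(v < bounds) + 1L]
  }
  label <- if (!isTRUE(qc_pass)) {
    "indeterminate"
  } else if (ci_rule == "within_bin" && !is.null(r_ci95) &&
             !anyNA(r_ci95) && bin_of(r_ci95[1]) != bin_of(r_ci95[2])) {
    "indeterminate"
  } else {
    bin_of(r)
  }
  structure(list(r = r,
                 r_ci95 = if (is.null(r_ci95)) c(NA_real_, NA_real_) else r_ci95,
                 degree_label = label, qc_pass = isTRUE(qc_pass)),
            class = "relatedness_call")
}

#' @export
print.relatedness_call <- function(x, ...) {
  cat(sprintf("r = %.4f [%.4f, %.4f] -> %s%s\n", x$r, x$r_ci95[1],
              x$r_ci95[2], x$degree_label,
              if (!x$qc_pass) " (QC fail)" else ""))
  invisible(x)
}

#' Full mismatch-rate kinship analysis for a list of pairs
#'
#' Computes baselines from the unrelated pairs, then for each query pair the
#' mismatch rate, relatedness coefficient and degree call.
#'
#' @param x a [genotype_matrix()].
#' @param pairs two-column matrix / data.frame of query sample-id pairs.
#' @param unrelated_pairs as in [estimate_baselines()].
#' @param observed_identical optional identical-endpoint override.
#' @param blocks,min_snps,seed see [pairwise_mismatch()].
#' @param ci_rule see [classify_degree()].
#' @return data.frame with one row per query pair: mismatch rate, CI, r,
#'   r CI, degree label, overlap count, QC flag; baselines as attributes
#'   `m_unrelated` / `m_identical`.
#' @export
kinship_analysis <- function(x, pairs, unrelated_pairs,
                             observed_identical = NULL, blocks = NULL,
                             min_snps = 10000L, seed = 1L,
                             ci_rule = "point") {
  if (is.null(blocks)) blocks <- make_blocks(x)
  bl <- estimate_baselines(x, unrelated_pairs, observed_identical,
                           blocks = blocks, min_snps = min_snps, seed = seed)
  pr <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pr)), function(i) {
    mm <- pairwise_mismatch(x, pr[i, 1], pr[i, 2], blocks = blocks,
                            min_snps = min_snps, seed = seed)
    rc <- relatedness_coefficient(mm, bl$m_unrelated, bl$m_identical)
    call <- classify_degree(rc$r, rc$ci95, qc_pass = mm$qc_pass,
                            ci_rule = ci_rule)
    data.frame(sample_a = pr[i, 1], sample_b = pr[i, 2],
               n_overlap = mm$n_overlap, mismatch_rate = mm$rate,
               mismatch_se = mm$std_error,
               mismatch_lo = mm$ci95[1], mismatch_hi = mm$ci95[2],
               r = rc$r, r_se = rc$se, r_lo = rc$ci95[1], r_hi = rc$ci95[2],
               degree = call$degree_label, qc_pass = mm$qc_pass,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "m_unrelated") <- bl$m_unrelated
  attr(out, "m_identical") <- bl$m_identical
  out
}

#' Degree-recovery simulation experiment
#'
#' The calibration experiment behind the kinship method: gene-drop
#' `n_pairs` replicate pairs per template on a fresh founder panel,
#' pseudo-haploidise both members, estimate the unrelated baseline from
#' `n_unrelated` simulated unrelated pairs (identical endpoint =
#' `m_unrelated / 2`), and convert every pair's mismatch rate into a
#' relatedness coefficient. With clean sampling the mean r per template
#' recovers the expected genome-sharing fraction (1 for twins, 1/8 for
#' third degree, 1/16 for fourth degree, ...).
#'
#' @param templates character vector of template names
#'   ([pedigree_templates()]).
#' @param n_pairs replicate pairs per template.
#' @param n_snps panel size.
#' @param n_unrelated unrelated pairs for the baseline.
#' @param sampling a [sampling_model()].
#' @param seed integer master seed.
#' @return list: `m_unrelated`, `unrelated_rates` (per-pair), and `per_template`
#'   — a named list of data.frames with per-pair `mismatch_rate` and `r` —
#'   plus `summary`, a data.frame of per-template mean r, SE of the mean and
#'   the expected share.
#' @export
simulate_degree_recovery <- function(templates, n_pairs = 200,
                                     n_snps = 100000L, n_unrelated = 100,
                                     sampling = sampling_model(), seed = 1L) {
  panel <- simulate_founders(founder_model(as.integer(n_snps), seed = seed))
  pair_rate <- function(template, k) {
    sp <- gene_drop(template, panel, seed = substream_seed(seed, 40000 + k))
    a <- pseudo_haploidize(sp$genotype_a, sampling,
                           seed = substream_seed(seed, 50000 + k))
    b <- pseudo_haploidize(sp$genotype_b, sampling,
                           seed = substream_seed(seed, 60000 + k))
    ov <- a != 9L & b != 9L
    mean(a[ov] != b[ov])
  }
  un_rates <- vapply(seq_len(n_unrelated), function(i)
    pair_rate("unrelated", i), numeric(1))
  m_un <- mean(un_rates)
  tt <- pedigree_templates()
  per_template <- list()
  summary_rows <- list()
  for (j in seq_along(templates)) {
    tm <- templates[j]
    rates <- vapply(seq_len(n_pairs), function(i)
      pair_rate(tm, 1000 * j + i), numeric(1))
    r <- (m_un - rates) / (m_un - m_un / 2)
    per_template[[tm]] <- data.frame(mismatch_rate = rates, r = r)
    summary_rows[[tm]] <- data.frame(
      template = tm, mean_r = mean(r),
      se_r = stats::sd(r) / sqrt(n_pairs),
      expected_share = tt$expected_share[tt$name == tm],
      n_pairs = n_pairs, stringsAsFactors = FALSE)
  }
  list(m_unrelated = m_un, unrelated_rates = un_rates,
       per_template = per_template,
       summary = do.call(rbind, summary_rows))
}

#' Genetic sex from X/Y read counts
#'
#' The fraction of sex-chromosome reads aligning to Y,
#' `r_y = n_y / (n_x + n_y)`, calls XY (male) above `xy_min` and XX
#' (female) below `xx_max`; in between (or with no reads) the call is
#' indeterminate. Default thresholds 0.075 / 0.016 follow common ancient-DNA
#' shotgun-sexing practice.
#'
#' @param n_x_reads,n_y_reads non-negative read counts.
#' @param xy_min,xx_max thresholds on `r_y`.
#' @return object of class `sex_call`: `n_x_reads`, `n_y_reads`, `r_y`,
#'   `call`.
#' @export
sex_from_counts <- function(n_x_reads, n_y_reads, xy_min = 0.075,
                            xx_max = 0.016) {
  if (n_x_reads < 0 || n_y_reads < 0) stop("read counts must be non-negative",
                                           call. = FALSE)
  tot <- n_x_reads + n_y_reads
  if (tot == 0) {
    warning("no reads on X or Y: sex indeterminate")
    return(structure(list(n_x_reads = n_x_reads, n_y_reads = n_y_reads,
                          r_y = NA_real_, call = "indeterminate"),
                     class = "sex_call"))
  }
  r_y <- n_y_reads / tot
  call <- if (r_y >= xy_min) "XY" else if (r_y <= xx_max) "XX" else
    "indeterminate"
  structure(list(n_x_reads = n_x_reads, n_y_reads = n_y_reads, r_y = r_y,
                 call = call), class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("r_y = %s (X %d, Y %d) -> %s\n",
              format(x$r_y, digits = 4), x$n_x_reads, x$n_y_reads, x$call))
  invisible(x)
}
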