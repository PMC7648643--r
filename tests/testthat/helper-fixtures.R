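# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# a small valid genotype matrix with arbitrary (possibly random) calls
toy_matrix <- function(calls, chrom = NULL, ploidy = NULL) {
  calls <- as.matrix(calls)
  L <- nrow(calls); S <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", L)
  snp <- data.frame(snp_id = paste0("rs", seq_len(L)), chrom = chrom,
                    gpos = 0, pos = ave(seq_len(L), chrom, FUN = seq_along) * 100L,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  ind <- data.frame(sample_id = paste0("s", seq_len(S)), sex = "U",
                    population = "pop", stringsAsFactors = FALSE)
  genotype_matrix(calls, snp, ind, ploidy = ploidy)
}

# random pseudo-haploid matrix for round-trip / oracle tests
random_matrix <- function(L, S, miss = 0.2, seed = 1, n_chrom = 2) {
  set.seed(seed)
  calls <- matrix(sample(c(0L, 2L), L * S, replace = TRUE), L, S)
  calls[matrix(runif(L * S) < miss, L, S)] <- 9L
  chrom <- as.character(rep(seq_len(n_chrom), length.out = L)[order(
    rep(seq_len(n_chrom), length.out = L))])
  toy_matrix(calls, chrom = chrom, ploidy = "pseudohaploid")
}

# brute-force per-SNP f-statistic oracle, independent of the fstats code
# path: plain loops over SNPs and samples
oracle_pop_freq <- function(gm, pop, j) {
  alt <- 0; tot <- 0
  for (s in pop) {
    cc <- gm$calls[j, s]
    if (cc != 9L) { alt <- alt + cc; tot <- tot + 2 }
  }
  if (tot == 0) NA_real_ else alt / tot
}

oracle_f3 <- function(gm, o, a, b) {
  terms <- c()
  for (j in seq_len(nrow(gm$calls))) {
    fo <- oracle_pop_freq(gm, o, j)
    fa <- oracle_pop_freq(gm, a, j)
    fb <- oracle_pop_freq(gm, b, j)
    if (!is.na(fo) && !is.na(fa) && !is.na(fb)) {
      terms <- c(terms, (fo - fa) * (fo - fb))
    }
  }
  mean(terms)
}

oracle_f4 <- function(gm, a, b, c, d) {
  terms <- c()
  for (j in seq_len(nrow(gm$calls))) {
    f <- c(oracle_pop_freq(gm, a, j), oracle_pop_freq(gm, b, j),
           oracle_pop_freq(gm, c, j), oracle_pop_freq(gm, d, j))
    if (!anyNA(f)) terms <- c(terms, (f[1] - f[2]) * (f[3] - f[4]))
  }
  mean(terms)
}
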