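# Synthetic-data generator: Hardy-Weinberg founder panels, pedigree
# gene-dropping with Poisson recombination, and pseudo-haploid sampling with
# missingness / error / contamination. This is the stated statistical world
# the kinship and f-statistic analyses assume; it makes no attempt at
# coalescent ancestry or population structure.

#' Pedigree templates and their expected genome sharing
#'
#' Canonical relationship templates with expected genome-sharing fraction
#' (k2 + k1/2) and degree of relatedness. Degree bindings: 1st degree =
#' parent/offspring, 2nd = avuncular, 3rd = first cousins, 4th = first
#' cousins once removed. `second_cousin` (expected share 1/32, degree 5 in
#' the usual counting) is provided for completeness but sits outside the
#' degree-0..4 classification bins.
#'
#' @format data.frame with columns `name`, `expected_share`, `degree`.
#' @export
pedigree_templates <- function() {
  data.frame(
    name = c("twin", "parent_offspring", "full_sib", "half_sib", "avuncular",
             "first_cousin", "first_cousin_once_removed", "second_cousin",
             "unrelated"),
    expected_share = c(1, 1 / 2, 1 / 2, 1 / 4, 1 / 4, 1 / 8, 1 / 16, 1 / 32, 0),
    degree = c(0L, 1L, 1L, 2L, 2L, 3L, 4L, NA_integer_, NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Default chromosome map
#'
#' 22 autosomes of 1.5 Morgan each with (as near as possible) equal SNP
#' counts; a sex-averaged desk-scale stand-in for the human autosomal map.
#'
#' @param n_snps total number of SNPs to distribute.
#' @param n_chrom number of autosomes.
#' @param morgans genetic length per chromosome.
#' @return data.frame with columns `chrom`, `length_morgans`, `n_snps`.
#' @export
default_chromosome_map <- function(n_snps, n_chrom = 22, morgans = 1.5) {
  n_chrom <- min(n_chrom, n_snps)
  base <- n_snps %/% n_chrom
  extra <- n_snps %% n_chrom
  data.frame(
    chrom = as.character(seq_len(n_chrom)),
    length_morgans = rep(morgans, n_chrom),
    n_snps = base + as.integer(seq_len(n_chrom) <= extra),
    stringsAsFactors = FALSE
  )
}

#' Founder-population model
#'
#' Describes the panel from which founder haplotypes are drawn: the number
#' of SNPs, their arrangement on chromosomes, and the law of the per-SNP
#' alternative-allele frequency. Supported laws: `uniform(a, b)` and
#' `beta(shape1, shape2)`. The law must place its mass inside (0, 1);
#' degenerate point masses at 0 or 1 are rejected.
#'
#' @param n_snps positive integer.
#' @param chromosome_map as from [default_chromosome_map()].
#' @param freq_law list with `law` in `{"uniform","beta"}` and numeric
#'   parameters `a`,`b` (uniform) or `shape1`,`shape2` (beta). Default
#'   uniform(0.05, 0.95), a crude stand-in for an ascertained capture panel.
#' @param seed integer seed; all downstream randomness derives from it.
#' @return object of class `founder_model`.
#' @export
founder_model <- function(n_snps,
                          chromosome_map = default_chromosome_map(n_snps),
                          freq_law = list(law = "uniform", a = 0.05, b = 0.95),
                          seed = 1L) {
  stopifnot(n_snps >= 1)
  if (sum(chromosome_map$n_snps) != n_snps) {
    stop("chromosome map SNP counts sum to ", sum(chromosome_map$n_snps),
         ", expected ", n_snps, call. = FALSE)
  }
  if (identical(freq_law$law, "uniform")) {
    a <- freq_law$a; b <- freq_law$b
    if (!(a <= b) || b <= 0 || a >= 1) {
      stop("degenerate uniform frequency law: mass must lie inside (0,1)",
           call. = FALSE)
    }
  } else if (identical(freq_law$law, "beta")) {
    if (freq_law$shape1 <= 0 || freq_law$shape2 <= 0) {
      stop("beta shapes must be positive", call. = FALSE)
    }
  } else {
    stop("unknown frequency law: ", freq_law$law, call. = FALSE)
  }
  structure(list(n_snps = as.integer(n_snps), chromosome_map = chromosome_map,
                 freq_law = freq_law, seed = as.integer(seed)),
            class = "founder_model")
}

# deterministic substream seeds from one global seed, kept < 2^31
substream_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 16807) %% 2147483629
}

#' Simulate a founder panel
#'
#' Draws per-SNP alternative-allele frequencies from the model's law. A
#' founder haplotype carries an independent Bernoulli(p_j) allele at SNP j
#' (Hardy-Weinberg, linkage equilibrium). Deterministic under the model
#' seed.
#'
#' @param model a [founder_model()].
#' @return object of class `founder_panel` with elements `freqs` (length
#'   `n_snps`), `model`, and per-chromosome SNP index ranges.
#' @export
simulate_founders <- function(model) {
  stopifnot(inherits(model, "founder_model"))
  set.seed(substream_seed(model$seed, 1))
  fl <- model$freq_law
  p <- switch(fl$law,
    uniform = stats::runif(model$n_snps, fl$a, fl$b),
    beta = stats::rbeta(model$n_snps, fl$shape1, fl$shape2)
  )
  # genetic positions: SNPs equally spaced along each chromosome
  cm <- model$chromosome_map
  ends <- cumsum(cm$n_snps)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  gpos <- numeric(model$n_snps)
  for (i in seq_len(nrow(cm))) {
    n <- cm$n_snps[i]
    gpos[starts[i]:ends[i]] <- if (n == 1) cm$length_morgans[i] / 2 else
      seq(0, cm$length_morgans[i], length.out = n)
  }
  structure(list(freqs = p, model = model, chrom_start = starts,
                 chrom_end = ends, gpos = gpos),
            class = "founder_panel")
}

#' Draw diploid founder genotypes
#'
#' @param panel a [simulate_founders()] panel.
#' @param n number of founder individuals.
#' @param seed integer seed.
#' @return integer matrix, SNPs x n, codes 0/1/2.
#' @export
founder_genotypes <- function(panel, n, seed = panel$model$seed) {
  set.seed(substream_seed(seed, 2))
  L <- panel$model$n_snps
  m <- matrix(stats::rbinom(L * n, 2L, panel$freqs), nrow = L, ncol = n)
  storage.mode(m) <- "integer"
  m
}

# one founder individual: two haplotypes (allele vectors) with globally
# unique origin labels used for identity-by-descent tracking
new_founder <- function(panel, next_id) {
  L <- panel$model$n_snps
  list(
    hap = list(
      list(allele = as.integer(stats::rbinom(L, 1L, panel$freqs)),
           origin = rep(next_id, L)),
      list(allele = as.integer(stats::rbinom(L, 1L, panel$freqs)),
           origin = rep(next_id + 1L, L))
    )
  )
}

# one meiosis: recombine a parent's two haplotypes. Crossovers are a Poisson
# process on the genetic map (no interference), independently per chromosome.
meiosis <- function(parent, panel) {
  L <- panel$model$n_snps
  allele <- integer(L)
  origin <- integer(L)
  cm <- panel$model$chromosome_map
  for (i in seq_len(nrow(cm))) {
    idx <- panel$chrom_start[i]:panel$chrom_end[i]
    len <- cm$length_morgans[i]
    k <- stats::rpois(1, len)
    xo <- sort(stats::runif(k, 0, len))
    start <- sample.int(2L, 1L)
    seg <- (start - 1L + findInterval(panel$gpos[idx], xo)) %% 2L + 1L
    pick1 <- seg == 1L
    allele[idx] <- ifelse(pick1, parent$hap[[1]]$allele[idx],
                          parent$hap[[2]]$allele[idx])
    origin[idx] <- ifelse(pick1, parent$hap[[1]]$origin[idx],
                          parent$hap[[2]]$origin[idx])
  }
  list(allele = allele, origin = origin)
}

mate <- function(pa, pb, panel) {
  list(hap = list(meiosis(pa, panel), meiosis(pb, panel)))
}

genotype_of <- function(ind) {
  as.integer(ind$hap[[1]]$allele + ind$hap[[2]]$allele)
}

# realized IBD share between two non-inbred individuals: per SNP the size of
# the maximum matching between their haplotype origin labels, averaged and
# halved. Within an individual the two origins always differ (no loops in
# any template pedigree), so the matching is max of the two pairings.
realized_ibd <- function(a, b) {
  a1 <- a$hap[[1]]$origin; a2 <- a$hap[[2]]$origin
  b1 <- b$hap[[1]]$origin; b2 <- b$hap[[2]]$origin
  m1 <- (a1 == b1) + (a2 == b2)
  m2 <- (a1 == b2) + (a2 == b1)
  mean(pmax(m1, m2)) / 2
}

#' Gene-drop a relationship template
#'
#' Builds the named pedigree explicitly from fresh founders drawn on the
#' panel, drops haplotypes through meioses with Poisson crossovers (no
#' interference, sex-averaged map) and returns the focal pair with its
#' realized identity-by-descent sharing. The `twin` template duplicates one
#' simulated child (monozygotic twins share their entire genome);
#' `unrelated` pairs two children of disjoint founder couples.
#'
#' @param template a template name from [pedigree_templates()].
#' @param panel a [simulate_founders()] panel.
#' @param seed integer seed for this drop.
#' @return object of class `simulated_pair`: `genotype_a`, `genotype_b`
#'   (diploid codes 0/1/2), `realized_ibd_share`, `template`,
#'   `expected_share`.
#' @export
gene_drop <- function(template, panel, seed = panel$model$seed) {
  tt <- pedigree_templates()
  row <- tt[tt$name == template, ]
  if (nrow(row) != 1) stop("unknown pedigree template: ", template,
                           call. = FALSE)
  set.seed(substream_seed(seed, 3))
  nf <- function(id) new_founder(panel, id)
  pair <- switch(template,
    twin = {
      c1 <- mate(nf(1L), nf(3L), panel)
      list(c1, c1)
    },
    parent_offspring = {
      f1 <- nf(1L)
      list(f1, mate(f1, nf(3L), panel))
    },
    full_sib = {
      f1 <- nf(1L); f2 <- nf(3L)
      list(mate(f1, f2, panel), mate(f1, f2, panel))
    },
    half_sib = {
      f1 <- nf(1L)
      list(mate(f1, nf(3L), panel), mate(f1, nf(5L), panel))
    },
    avuncular = {
      f1 <- nf(1L); f2 <- nf(3L)
      s1 <- mate(f1, f2, panel); s2 <- mate(f1, f2, panel)
      list(s1, mate(s2, nf(5L), panel))
    },
    first_cousin = {
      f1 <- nf(1L); f2 <- nf(3L)
      s1 <- mate(f1, f2, panel); s2 <- mate(f1, f2, panel)
      list(mate(s1, nf(5L), panel), mate(s2, nf(7L), panel))
    },
    first_cousin_once_removed = {
      f1 <- nf(1L); f2 <- nf(3L)
      s1 <- mate(f1, f2, panel); s2 <- mate(f1, f2, panel)
      c1 <- mate(s1, nf(5L), panel); c2 <- mate(s2, nf(7L), panel)
      list(c1, mate(c2, nf(9L), panel))
    },
    second_cousin = {
      f1 <- nf(1L); f2 <- nf(3L)
      s1 <- mate(f1, f2, panel); s2 <- mate(f1, f2, panel)
      c1 <- mate(s1, nf(5L), panel); c2 <- mate(s2, nf(7L), panel)
      list(mate(c1, nf(9L), panel), mate(c2, nf(11L), panel))
    },
    unrelated = {
      list(mate(nf(1L), nf(3L), panel), mate(nf(5L), nf(7L), panel))
    }
  )
  structure(list(
    genotype_a = genotype_of(pair[[1]]),
    genotype_b = genotype_of(pair[[2]]),
    realized_ibd_share = realized_ibd(pair[[1]], pair[[2]]),
    template = template,
    expected_share = row$expected_share
  ), class = "simulated_pair")
}

#' Pseudo-haploid sampling model
#'
#' Emulates the random-read representation of low-coverage capture data:
#' per SNP a single sequencing read is sampled, so a diploid genotype
#' collapses to one allele, reported as a homozygote code (0 or 2).
#' Post-mortem damage is folded into a symmetric per-call error flip (the
#' mismatch-rate statistics downstream are allele-symmetric), and
#' contamination replaces the sampled allele by a draw from contaminant
#' allele frequencies.
#'
#' @param missing_rate probability a site is unobserved (emit 9).
#' @param error_rate probability an emitted allele is flipped.
#' @param contamination_rate probability the sampled allele is replaced by a
#'   contaminant draw.
#' @param contaminant_freqs per-SNP contaminant alt-allele frequencies
#'   (recycled); only used when `contamination_rate > 0`.
#' @return object of class `sampling_model`.
#' @export
sampling_model <- function(missing_rate = 0, error_rate = 0,
                           contamination_rate = 0, contaminant_freqs = 0.5) {
  pr <- c(missing_rate, error_rate, contamination_rate)
  if (any(pr < 0 | pr > 1)) stop("rates must be probabilities in [0,1]",
                                 call. = FALSE)
  structure(list(missing_rate = missing_rate, error_rate = error_rate,
                 contamination_rate = contamination_rate,
                 contaminant_freqs = contaminant_freqs),
            class = "sampling_model")
}

#' Pseudo-haploidise a diploid call vector
#'
#' @param diploid integer vector of codes in `{0,1,2,9}`.
#' @param sampling a [sampling_model()].
#' @param seed integer seed.
#' @return integer vector of codes in `{0,2,9}`.
#' @export
pseudo_haploidize <- function(diploid, sampling = sampling_model(),
                              seed = 1L) {
  if (!all(diploid %in% VALID_CALL_CODES)) {
    stop("diploid codes must be in {0,1,2,9}", call. = FALSE)
  }
  set.seed(substream_seed(seed, 4))
  L <- length(diploid)
  out <- integer(L)
  miss <- diploid == 9L | stats::runif(L) < sampling$missing_rate
  # sample one of the two alleles uniformly: het -> Bernoulli(1/2)
  allele <- integer(L)
  allele[diploid == 2L] <- 1L
  het <- diploid == 1L
  allele[het] <- as.integer(stats::runif(L)[het] < 0.5)
  if (sampling$contamination_rate > 0) {
    cf <- rep(sampling$contaminant_freqs, length.out = L)
    cont <- stats::runif(L) < sampling$contamination_rate
    contallele <- as.integer(stats::runif(L) < cf)
    allele[cont] <- contallele[cont]
  }
  if (sampling$error_rate > 0) {
    err <- stats::runif(L) < sampling$error_rate
    allele[err] <- 1L - allele[err]
  }
  out <- 2L * allele
  out[miss] <- 9L
  out
}

#' Simulate a panel of replicate pairs as a genotype matrix
#'
#' Convenience wrapper used by the pipeline driver and the acceptance
#' tests: gene-drops `n_pairs` replicates of one template, pseudo-haploidises
#' both members, and assembles a [genotype_matrix()] whose samples are named
#' `<template>_<i>_a` / `<template>_<i>_b`. The realized IBD share of each
#' pair is returned alongside as a manifest.
#'
#' @param template template name.
#' @param panel a [simulate_founders()] panel.
#' @param n_pairs number of replicate pairs.
#' @param sampling a [sampling_model()].
#' @param seed integer seed.
#' @return list with `matrix` (genotype_matrix) and `manifest` (data.frame
#'   pair ids and realized IBD).
#' @export
simulate_pair_panel <- function(template, panel, n_pairs,
                                sampling = sampling_model(), seed = 1L) {
  L <- panel$model$n_snps
  calls <- matrix(9L, nrow = L, ncol = 2 * n_pairs)
  ibd <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    sp <- gene_drop(template, panel, seed = substream_seed(seed, 100 + i))
    calls[, 2 * i - 1] <- pseudo_haploidize(sp$genotype_a, sampling,
                                            seed = substream_seed(seed, 7000 + i))
    calls[, 2 * i] <- pseudo_haploidize(sp$genotype_b, sampling,
                                        seed = substream_seed(seed, 8000 + i))
    ibd[i] <- sp$realized_ibd_share
  }
  ids <- as.vector(rbind(paste0(template, "_", seq_len(n_pairs), "_a"),
                         paste0(template, "_", seq_len(n_pairs), "_b")))
  snp <- panel_snp_table(panel)
  ind <- data.frame(sample_id = ids, sex = "U", population = template,
                    stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, snp, ind, ploidy = "pseudohaploid")
  manifest <- data.frame(pair = seq_len(n_pairs),
                         sample_a = ids[seq(1, 2 * n_pairs, 2)],
                         sample_b = ids[seq(2, 2 * n_pairs, 2)],
                         realized_ibd_share = ibd,
                         stringsAsFactors = FALSE)
  list(matrix = gm, manifest = manifest)
}

# SNP metadata table matching a founder panel's layout
panel_snp_table <- function(panel) {
  cm <- panel$model$chromosome_map
  chrom <- rep(cm$chrom, cm$n_snps)
  pos <- unlist(lapply(cm$n_snps, seq_len), use.names = FALSE) * 1000L
  data.frame(
    snp_id = paste0("snp", seq_len(panel$model$n_snps)),
    chrom = chrom, gpos = panel$gpos, pos = pos,
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
}
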