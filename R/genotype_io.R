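VALID_CALL_CODES <- c(0L, 1L, 2L, 9L)
VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")

#' Normalise chromosome labels
#'
#' Maps the tokens accepted on input (case-insensitive `x`, `y`, `mt`/`m`,
#' and the numeric EIGENSTRAT codes 23 = X, 24 = Y, 90 = MT) onto the
#' canonical label set `{1..22, X, Y, MT}`. Any other token is an error.
#'
#' @param chrom character vector of chromosome tokens.
#' @return character vector of canonical labels.
#' @export
normalize_chromosome <- function(chrom) {
  ch <- toupper(trimws(as.character(chrom)))
  ch[ch == "23"] <- "X"
  ch[ch == "24"] <- "Y"
  ch[ch %in% c("90", "M", "CHRMT", "CHRM")] <- "MT"
  ch <- sub("^CHR", "", ch)
  bad <- !(ch %in% VALID_CHROMOSOMES)
  if (any(bad)) {
    stop("invalid chromosome label(s): ",
         paste(unique(chrom[bad]), collapse = ", "), call. = FALSE)
  }
  ch
}

#' Construct a genotype matrix
#'
#' The central genetics container: per-SNP call codes for a set of samples,
#' plus SNP and sample metadata. Calls are stored as an integer matrix with
#' one row per SNP and one column per sample (the layout of an ASCII
#' EIGENSTRAT `.geno` file). Codes count alternative alleles: 0, 1, 2, with
#' 9 for missing. Pseudo-haploid samples (a single allele drawn at random
#' per covered site, the standard representation for low-coverage ancient
#' DNA) may only carry codes 0, 2 and 9.
#'
#' @param calls integer matrix, SNPs x samples, codes in `{0,1,2,9}`.
#' @param snp data.frame with columns `snp_id`, `chrom`, `gpos` (genetic
#'   position, Morgans; 0 if absent), `pos` (1-based physical position),
#'   `ref`, `alt` (single characters in A/C/G/T).
#' @param ind data.frame with columns `sample_id`, `sex` (`M`, `F` or `U`)
#'   and `population`.
#' @param ploidy character vector, one of `"diploid"`/`"pseudohaploid"` per
#'   sample, or a single value recycled. `NULL` infers per sample: a sample
#'   with at least one heterozygous call (code 1) is diploid, otherwise
#'   pseudo-haploid.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp, ind, ploidy = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(snp) != nrow(calls)) {
    stop("snp table has ", nrow(snp), " rows but calls has ", nrow(calls),
         call. = FALSE)
  }
  if (nrow(ind) != ncol(calls)) {
    stop("ind table has ", nrow(ind), " rows but calls has ", ncol(calls),
         " columns", call. = FALSE)
  }
  need_snp <- c("snp_id", "chrom", "gpos", "pos", "ref", "alt")
  if (!all(need_snp %in% names(snp))) {
    stop("snp table must have columns: ", paste(need_snp, collapse = ", "),
         call. = FALSE)
  }
  need_ind <- c("sample_id", "sex", "population")
  if (!all(need_ind %in% names(ind))) {
    stop("ind table must have columns: ", paste(need_ind, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ind$sample_id)) {
    stop("duplicate sample_id in ind table", call. = FALSE)
  }
  snp$chrom <- normalize_chromosome(snp$chrom)
  if (any(snp$pos < 0)) stop("negative physical position", call. = FALSE)
  if (any(!(toupper(snp$ref) %in% c("A", "C", "G", "T")) |
          !(toupper(snp$alt) %in% c("A", "C", "G", "T")))) {
    stop("alleles must be single characters in {A,C,G,T}", call. = FALSE)
  }
  if (any(snp$ref == snp$alt)) {
    stop("ref and alt allele identical at: ",
         paste(utils::head(snp$snp_id[snp$ref == snp$alt], 3), collapse = ", "),
         call. = FALSE)
  }
  # positions strictly increasing within each chromosome run
  for (ch in unique(snp$chrom)) {
    p <- snp$pos[snp$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch,
           call. = FALSE)
    }
  }
  bad <- matrix(!(calls %in% VALID_CALL_CODES), nrow = nrow(calls))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("illegal call code ", calls[bad][1], " at SNP row ", idx[1],
         ", sample column ", idx[2], call. = FALSE)
  }
  if (is.null(ploidy)) {
    has_het <- apply(calls == 1L, 2, any)
    ploidy <- ifelse(has_het, "diploid", "pseudohaploid")
  } else {
    ploidy <- rep(ploidy, length.out = ncol(calls))
  }
  if (!all(ploidy %in% c("diploid", "pseudohaploid"))) {
    stop("ploidy must be 'diploid' or 'pseudohaploid'", call. = FALSE)
  }
  ph_het <- ploidy == "pseudohaploid" & apply(calls == 1L, 2, any)
  if (any(ph_het)) {
    stop("heterozygous call (code 1) in pseudo-haploid sample(s): ",
         paste(ind$sample_id[ph_het], collapse = ", "), call. = FALSE)
  }
  dimnames(calls) <- list(snp$snp_id, ind$sample_id)
  structure(
    list(calls = calls, snp = as.data.frame(snp, stringsAsFactors = FALSE),
         ind = as.data.frame(ind, stringsAsFactors = FALSE),
         ploidy = stats::setNames(ploidy, ind$sample_id)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "SNPs x", ncol(x$calls), "samples\n")
  cat("  chromosomes:", paste(unique(x$snp$chrom), collapse = " "), "\n")
  cat("  samples:", paste(utils::head(x$ind$sample_id, 6), collapse = " "),
      if (ncol(x$calls) > 6) "..." else "", "\n")
  miss <- mean(x$calls == 9L)
  cat(sprintf("  missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of SNPs / samples in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_snps <- function(x) nrow(x$calls)

#' @rdname n_snps
#' @export
n_samples <- function(x) ncol(x$calls)

sample_column <- function(x, sample_id) {
  j <- match(sample_id, x$ind$sample_id)
  if (is.na(j)) stop("unknown sample id: ", sample_id, call. = FALSE)
  j
}

#' Read an ASCII EIGENSTRAT triplet
#'
#' Reads the `.geno`/`.snp`/`.ind` triplet used for 1240K-capture style
#' data. Only the ASCII geno dialect is supported: one row per SNP, one
#' digit per sample, digits in `{0,1,2,9}`. Packed binary geno files are
#' rejected.
#'
#' @param prefix path prefix; `<prefix>.geno` etc. are read unless the
#'   individual paths are given.
#' @param geno,snp,ind explicit file paths (override `prefix`).
#' @param ploidy as in [genotype_matrix()].
#' @return a [genotype_matrix()].
#' @export
read_eigenstrat <- function(prefix = NULL,
                            geno = paste0(prefix, ".geno"),
                            snp = paste0(prefix, ".snp"),
                            ind = paste0(prefix, ".ind"),
                            ploidy = NULL) {
  for (f in c(geno, snp, ind)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  glines <- readLines(geno)
  if (length(glines) > 0 && startsWith(glines[1], "GENO")) {
    stop("packed binary EIGENSTRAT geno files are not supported; ",
         "convert to the ASCII dialect", call. = FALSE)
  }
  ind_df <- utils::read.table(ind, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("sample_id", "sex", "population"),
                              colClasses = "character")
  snp_df <- utils::read.table(snp, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("snp_id", "chrom", "gpos", "pos",
                                            "ref", "alt"),
                              colClasses = c("character", "character",
                                             "numeric", "integer",
                                             "character", "character"))
  if (length(glines) != nrow(snp_df)) {
    stop("geno file has ", length(glines), " rows but snp file describes ",
         nrow(snp_df), " SNPs", call. = FALSE)
  }
  ns <- nrow(ind_df)
  widths <- nchar(glines)
  if (length(glines) > 0 && any(widths != ns)) {
    bad <- which(widths != ns)[1]
    stop("geno row ", bad, " has ", widths[bad], " characters but ind file ",
         "describes ", ns, " samples", call. = FALSE)
  }
  if (length(glines) > 0) {
    digits <- unlist(strsplit(glines, "", fixed = TRUE), use.names = FALSE)
    ok <- digits %in% c("0", "1", "2", "9")
    if (!all(ok)) {
      k <- which(!ok)[1]
      stop("illegal geno digit '", digits[k], "' at SNP row ",
           (k - 1) %/% ns + 1, ", sample column ", (k - 1) %% ns + 1,
           call. = FALSE)
    }
    calls <- matrix(as.integer(digits), nrow = length(glines), ncol = ns,
                    byrow = TRUE)
  } else {
    calls <- matrix(integer(0), nrow = 0, ncol = ns)
  }
  genotype_matrix(calls, snp_df, ind_df, ploidy = ploidy)
}

#' Write an ASCII EIGENSTRAT triplet
#'
#' Inverse of [read_eigenstrat()]; `read_eigenstrat(write_eigenstrat(x))`
#' is the identity, and re-writing a matrix read from files produced here
#' reproduces them byte-identically.
#'
#' @param x a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return invisibly, a character vector of the three file paths.
#' @export
write_eigenstrat <- function(x, prefix) {
  stopifnot(inherits(x, "genotype_matrix"))
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  g <- if (nrow(x$calls) > 0) {
    apply(x$calls, 1, paste0, collapse = "")
  } else character(0)
  writeLines(g, paths[1])
  snp_lines <- sprintf("%s\t%s\t%.6f\t%d\t%s\t%s",
                       x$snp$snp_id, x$snp$chrom, x$snp$gpos,
                       as.integer(x$snp$pos), x$snp$ref, x$snp$alt)
  writeLines(snp_lines, paths[2])
  ind_lines <- sprintf("%s\t%s\t%s", x$ind$sample_id, x$ind$sex,
                       x$ind$population)
  writeLines(ind_lines, paths[3])
  invisible(paths)
}

#' Indices of SNPs covered in both samples
#'
#' Listwise overlap for pairwise statistics: SNP indices (ascending) at
#' which neither sample has the missing code 9. Symmetric in its sample
#' arguments.
#'
#' @param x a [genotype_matrix()].
#' @param sample_a,sample_b sample ids.
#' @return integer vector of SNP indices.
#' @export
overlap_mask <- function(x, sample_a, sample_b) {
  a <- x$calls[, sample_column(x, sample_a)]
  b <- x$calls[, sample_column(x, sample_b)]
  unname(which(a != 9L & b != 9L))
}
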