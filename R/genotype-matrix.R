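#' Construct a genotype matrix
#'
#' The central in-memory container of the package: an ordered set of variant
#' sites by an ordered set of samples, where every cell carries an unphased
#' genotype call plus its supporting read depth (DP) and phred-scaled
#' genotype quality (GQ). Missing calls are `NA` in all three layers.
#'
#' Genotypes are stored as normalized allele-index strings (`"0/0"`, `"0/1"`,
#' `"1/1"`, `"1/2"`, ...): unphased, allele indices sorted ascending, so
#' `"1/0"` and `"0|1"` both normalize to `"0/1"`. Phase is never interpreted.
#'
#' @param samples character vector of unique sample identifiers.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated string for multi-allelic sites).
#' @param gt character matrix (variants x samples) of genotype strings,
#'   `NA` for missing calls.
#' @param dp,gq numeric matrices (variants x samples) of read depth and
#'   genotype quality; `NA` where unknown or where the call is missing.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, gt, dp = NULL, gq = NULL) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicated sample ids")
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  variants <- data.frame(chrom = as.character(variants$chrom),
                         pos = as.integer(variants$pos),
                         ref = as.character(variants$ref),
                         alt = as.character(variants$alt),
                         stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  if (any(!nzchar(variants$alt) | is.na(variants$alt)))
    stop("every variant must have at least one alt allele")
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key))
    stop("duplicated variant (chrom, pos, ref, alt)")
  nv <- nrow(variants); ns <- length(samples)
  gt <- matrix(as.character(gt), nrow = nv, ncol = ns)
  if (is.null(dp)) dp <- matrix(NA_real_, nv, ns)
  if (is.null(gq)) gq <- matrix(NA_real_, nv, ns)
  dp <- matrix(as.numeric(dp), nv, ns)
  gq <- matrix(as.numeric(gq), nv, ns)
  if (any(dp < 0, na.rm = TRUE)) stop("read depth must be >= 0")
  if (any(gq < 0, na.rm = TRUE)) stop("genotype quality must be >= 0")
  gt[] <- normalize_gt(gt)
  # missing calls carry no usable depth/quality
  dp[is.na(gt)] <- NA_real_
  gq[is.na(gt)] <- NA_real_
  dimnames(gt) <- dimnames(dp) <- dimnames(gq) <- list(NULL, samples)
  structure(list(samples = samples, variants = variants,
                 gt = gt, dp = dp, gq = gq),
            class = "genotype_matrix")
}

#' Normalize genotype strings
#'
#' Lower-level helper: maps raw VCF GT strings to the package's canonical
#' unphased representation. `"."`, `"./."` and `".|."` become `NA`.
#' @param x character vector of GT strings.
#' @return character vector of normalized genotypes.
#' @keywords internal
normalize_gt <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & x != "" & x != "."
  if (!any(ok)) return(out)
  parts <- strsplit(x[ok], "[/|]")
  out[ok] <- vapply(parts, function(p) {
    if (any(p == "." | p == "")) return(NA_character_)
    a <- sort(as.integer(p))
    paste(a, collapse = "/")
  }, character(1))
  out
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$variants), length(x$samples))

#' Number of variants / samples in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_variants <- function(x) nrow(x$variants)

#' @rdname n_variants
#' @export
n_samples <- function(x) length(x$samples)

#' Per-variant and per-sample call rates
#'
#' The per-variant call rate is the fraction of samples with a non-missing
#' genotype at that variant (missing samples count in the denominator); the
#' per-sample call rate is the fraction of variants non-missing for that
#' sample.
#'
#' @param x a `genotype_matrix`.
#' @return numeric vector in \[0, 1\].
#' @export
variant_call_rate <- function(x) rowMeans(!is.na(x$gt))

#' @rdname variant_call_rate
#' @export
sample_call_rate <- function(x) colMeans(!is.na(x$gt))

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param variants integer or logical index of variants to keep.
#' @param samples integer, logical, or character index of samples to keep.
#' @return a `genotype_matrix`.
#' @export
subset_matrix <- function(x, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(n_variants(x)) else variants
  si <- if (is.null(samples)) seq_along(x$samples) else samples
  if (is.character(si)) si <- match(si, x$samples)
  genotype_matrix(x$samples[si], x$variants[vi, , drop = FALSE],
                  x$gt[vi, si, drop = FALSE],
                  x$dp[vi, si, drop = FALSE],
                  x$gq[vi, si, drop = FALSE])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples\n",
              n_variants(x), n_samples(x)))
  cat(sprintf("  mean per-variant call rate: %.3f\n",
              mean(variant_call_rate(x))))
  invisible(x)
}

#' @method all.equal genotype_matrix
#' @export
all.equal.genotype_matrix <- function(target, current, ...) {
  msgs <- character(0)
  if (!identical(target$samples, current$samples))
    msgs <- c(msgs, "sample ids differ")
  if (!isTRUE(all.equal(target$variants, current$variants, ...)))
    msgs <- c(msgs, "variant tables differ")
  if (!identical(target$gt, current$gt)) msgs <- c(msgs, "genotypes differ")
  if (!isTRUE(all.equal(target$dp, current$dp, ...))) msgs <- c(msgs, "DP differs")
  if (!isTRUE(all.equal(target$gq, current$gq, ...))) msgs <- c(msgs, "GQ differs")
  if (length(msgs)) msgs else TRUE
}

# number of alt alleles per variant
n_alt_alleles <- function(x) {
  lengths(strsplit(x$variants$alt, ",", fixed = TRUE))
}

# genotype class of biallelic calls relative to a matrix's own ref/alt:
# "MM" hom-ref, "Mm" het, "mm" hom-alt, NA for missing or multi-allelic codes
gt_class <- function(g) {
  cls <- rep(NA_character_, length(g))
  cls[g == "0/0"] <- "MM"
  cls[g == "0/1"] <- "Mm"
  cls[g == "1/1"] <- "mm"
  cls
}
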