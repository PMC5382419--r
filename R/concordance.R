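COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Match variant sites between two genotype matrices
#'
#' Variants are matched on (chromosome, position) and their alleles
#' reconciled:
#' \itemize{
#'   \item identical ref/alt — compared directly;
#'   \item swapped ref/alt — the second matrix's genotype codes are flipped
#'     (hom-ref becomes hom-alt and vice versa);
#'   \item complementary alleles (a strand flip), directly or swapped —
#'     handled the same way, but only when unambiguous: A/T and C/G SNPs,
#'     whose complement equals their own swap, are excluded;
#'   \item anything else — excluded.
#' }
#' Excluded sites are reported in the `excluded` attribute.
#'
#' @param a,b two [genotype_matrix()] objects sharing at least one sample.
#' @return data.frame with columns `idx_a`, `idx_b`, `flip` (logical: do
#'   `b`'s genotype codes refer to `a`'s alleles in reverse?).
#' @export
shared_markers <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  if (length(intersect(a$samples, b$samples)) == 0L)
    stop("the two matrices share no sample ids")
  key_a <- paste(a$variants$chrom, a$variants$pos)
  key_b <- paste(b$variants$chrom, b$variants$pos)
  idx_b <- match(key_a, key_b)
  idx_a <- which(!is.na(idx_b))
  idx_b <- idx_b[idx_a]
  if (length(idx_a) == 0L)
    return(structure(data.frame(idx_a = integer(0), idx_b = integer(0),
                                flip = logical(0)),
                     excluded = integer(0)))
  ra <- a$variants$ref[idx_a]; aa <- a$variants$alt[idx_a]
  rb <- b$variants$ref[idx_b]; ab <- b$variants$alt[idx_b]
  comp <- function(x) {
    out <- COMPLEMENT[x]
    out[is.na(out)] <- NA_character_
    unname(out)
  }
  simple <- nchar(ra) == 1L & nchar(aa) == 1L & nchar(rb) == 1L & nchar(ab) == 1L
  ambiguous <- simple & comp(ra) == aa   # A/T and C/G SNPs
  direct <- ra == rb & aa == ab
  # a swapped A/T or C/G SNP is indistinguishable from a strand flip of the
  # same SNP, so swap-based reconciliation is refused for ambiguous alleles
  swapped <- ra == ab & aa == rb & !direct & !(ambiguous %in% TRUE)
  cdirect <- simple & !ambiguous & comp(ra) == rb & comp(aa) == ab & !direct & !swapped
  cswapped <- simple & !ambiguous & comp(ra) == ab & comp(aa) == rb &
              !direct & !swapped & !cdirect
  keep <- direct | swapped | (!is.na(cdirect) & cdirect) |
          (!is.na(cswapped) & cswapped)
  keep[is.na(keep)] <- FALSE
  excluded <- idx_a[!keep]
  if (length(excluded))
    message(length(excluded),
            " shared position(s) excluded: irreconcilable or strand-ambiguous alleles")
  out <- data.frame(idx_a = idx_a[keep], idx_b = idx_b[keep],
                    flip = (swapped | (!is.na(cswapped) & cswapped))[keep])
  attr(out, "excluded") <- excluded
  out
}

new_concordance_table <- function(per_variant, concordant, discordant) {
  conc <- sum(concordant); disc <- sum(discordant)
  structure(list(per_variant = per_variant,
                 concordant = concordant, discordant = discordant,
                 n_compared = conc + disc,
                 accuracy = if (conc + disc > 0) 100 * conc / (conc + disc)
                            else NA_real_),
            class = "concordance_table")
}

#' Build a concordance table from pre-tabulated counts
#'
#' Accepts concordant and discordant call counts stratified by the truth
#' genotype class (hom-ref `MM`, het `Mm`, hom-alt `mm`) and derives the
#' aggregate accuracy, `100 * concordant / (concordant + discordant)`.
#'
#' @param concordant,discordant numeric vectors of length 3, named or in
#'   the order `MM`, `Mm`, `mm`.
#' @return a `concordance_table`.
#' @examples
#' concordance_table(concordant = c(MM = 237, Mm = 16, mm = 0),
#'                   discordant = c(MM = 0, Mm = 0, mm = 0))$accuracy
#' @export
concordance_table <- function(concordant, discordant = c(0, 0, 0)) {
  cls <- c("MM", "Mm", "mm")
  fix <- function(x) {
    stopifnot(length(x) == 3L, all(x >= 0))
    if (is.null(names(x))) names(x) <- cls
    x[cls]
  }
  new_concordance_table(NULL, fix(concordant), fix(discordant))
}

#' Genotype concordance against a designated truth panel
#'
#' Compares genotype calls at markers shared between `query` and `truth`
#' (matched and allele-reconciled via [shared_markers()]) over the samples
#' the two panels share. Pairs where either side is missing are excluded.
#' Counts are stratified by the truth genotype class; the accuracy is
#' `100 * concordant / (concordant + discordant)`. The statistic is
#' directional: `truth` is taken as correct and the table is not
#' symmetrized.
#'
#' @param query a [genotype_matrix()] to be scored.
#' @param truth a [genotype_matrix()] assumed to carry true genotypes.
#' @param pairs optional pre-computed [shared_markers()] result.
#' @return a `concordance_table` with a per-variant count data.frame,
#'   per-class aggregate counts and the accuracy percentage. `NA` accuracy
#'   (with zero comparable pairs) signals an undefined statistic.
#' @export
concordance <- function(query, truth, pairs = NULL) {
  if (is.null(pairs)) pairs <- shared_markers(query, truth)
  if (nrow(pairs) == 0L)
    return(new_concordance_table(
      data.frame(), c(MM = 0, Mm = 0, mm = 0), c(MM = 0, Mm = 0, mm = 0)))
  samp <- intersect(query$samples, truth$samples)
  gq_ <- query$gt[pairs$idx_a, match(samp, query$samples), drop = FALSE]
  gt_ <- truth$gt[pairs$idx_b, match(samp, truth$samples), drop = FALSE]
  # express truth codes in the query's allele frame
  flip_rows <- which(pairs$flip)
  if (length(flip_rows)) {
    block <- gt_[flip_rows, , drop = FALSE]
    block[block == "0/0"] <- "x"
    block[block == "1/1"] <- "0/0"
    block[block == "x"] <- "1/1"
    gt_[flip_rows, ] <- block
  }
  cls <- gt_class(gt_)
  dim(cls) <- dim(gt_)
  comparable <- !is.na(gq_) & !is.na(cls)
  agree <- comparable & gq_ == gt_
  count_by_class <- function(m) {
    sapply(c("MM", "Mm", "mm"), function(k)
      rowSums(m & cls == k, na.rm = TRUE))
  }
  conc_m <- count_by_class(agree)
  disc_m <- count_by_class(comparable & !agree)
  if (nrow(pairs) == 1L) { conc_m <- t(conc_m); disc_m <- t(disc_m) }
  colnames(conc_m) <- paste0("conc_", c("MM", "Mm", "mm"))
  colnames(disc_m) <- paste0("disc_", c("MM", "Mm", "mm"))
  per_variant <- cbind(query$variants[pairs$idx_a, c("chrom", "pos"),
                                      drop = FALSE],
                       as.data.frame(conc_m), as.data.frame(disc_m))
  rownames(per_variant) <- NULL
  new_concordance_table(per_variant,
                        c(MM = sum(conc_m[, 1]), Mm = sum(conc_m[, 2]),
                          mm = sum(conc_m[, 3])),
                        c(MM = sum(disc_m[, 1]), Mm = sum(disc_m[, 2]),
                          mm = sum(disc_m[, 3])))
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("concordance_table\n")
  cat(sprintf("  concordant (MM/Mm/mm): %d / %d / %d\n",
              x$concordant[1], x$concordant[2], x$concordant[3]))
  cat(sprintf("  discordant (MM/Mm/mm): %d / %d / %d\n",
              x$discordant[1], x$discordant[2], x$discordant[3]))
  cat(sprintf("  accuracy: %s%%  (n = %d)\n",
              if (is.na(x$accuracy)) "undefined" else sprintf("%.1f", x$accuracy),
              x$n_compared))
  invisible(x)
}

#' Genotype accuracy across a QC grid
#'
#' Runs [concordance()] for every dataset of a [dataset_grid()] result,
#' reporting per configuration the number of markers shared with the truth
#' panel, the number of comparable (both-non-missing) calls examined, and
#' the accuracy percentage.
#'
#' @param grid a [dataset_grid()] result computed on the query matrix.
#' @param truth the truth [genotype_matrix()].
#' @return the grid's table with columns `shared_markers`, `n_calls_examined`
#'   and `accuracy` appended.
#' @export
accuracy_by_filter_grid <- function(grid, truth) {
  stopifnot(is.list(grid), !is.null(grid$datasets))
  res <- grid$table
  res$shared_markers <- NA_integer_
  res$n_calls_examined <- NA_integer_
  res$accuracy <- NA_real_
  for (i in seq_along(grid$datasets)) {
    ct <- suppressMessages(concordance(grid$datasets[[i]], truth))
    res$shared_markers[i] <- if (is.null(ct$per_variant)) 0L
                             else nrow(ct$per_variant)
    res$n_calls_examined[i] <- ct$n_compared
    res$accuracy[i] <- ct$accuracy
  }
  res
}
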