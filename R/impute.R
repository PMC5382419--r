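#' Combine a GBS panel with a dense anchor panel
#'
#' Reproduces the dense-panel merging design used for imputation
#' evaluation: anchor (array-style) variants that coincide with a GBS
#' variant on (chromosome, position) are removed from the anchor first, so
#' the merged panel contains each locus once and every retained anchor
#' locus is GBS-free; the merged variants are position-sorted and tagged by
#' origin. The pre-removal overlap is recorded as the evaluation loci —
#' the GBS variants whose imputed genotypes can later be scored against
#' the unaltered truth panel.
#'
#' Only samples present in both panels are kept (missing calls would
#' otherwise be introduced for panel-specific samples).
#'
#' @param gbs a GBS [genotype_matrix()].
#' @param anchor a dense-panel [genotype_matrix()].
#' @return a `combined_panel`: list with `matrix` (merged
#'   [genotype_matrix()]), `origin` (character vector `"GBS"`/`"anchor"`
#'   per merged variant) and `evaluation_loci` (data.frame `chrom`, `pos`).
#' @export
combine_panels <- function(gbs, anchor) {
  stopifnot(inherits(gbs, "genotype_matrix"),
            inherits(anchor, "genotype_matrix"))
  samp <- intersect(gbs$samples, anchor$samples)
  if (length(samp) == 0L) stop("the two panels share no sample ids")
  gbs <- subset_matrix(gbs, samples = samp)
  anchor <- subset_matrix(anchor, samples = samp)
  key_g <- paste(gbs$variants$chrom, gbs$variants$pos)
  key_a <- paste(anchor$variants$chrom, anchor$variants$pos)
  shared <- key_a %in% key_g
  eval_loci <- gbs$variants[key_g %in% key_a, c("chrom", "pos"), drop = FALSE]
  rownames(eval_loci) <- NULL
  anchor_kept <- subset_matrix(anchor, variants = !shared)
  variants <- rbind(gbs$variants, anchor_kept$variants)
  origin <- c(rep("GBS", n_variants(gbs)),
              rep("anchor", n_variants(anchor_kept)))
  gt <- rbind(gbs$gt, anchor_kept$gt)
  dp <- rbind(gbs$dp, anchor_kept$dp)
  gq <- rbind(gbs$gq, anchor_kept$gq)
  ord <- order(variants$chrom, variants$pos)
  merged <- genotype_matrix(samp, variants[ord, , drop = FALSE],
                            gt[ord, , drop = FALSE], dp[ord, , drop = FALSE],
                            gq[ord, , drop = FALSE])
  structure(list(matrix = merged, origin = origin[ord],
                 evaluation_loci = eval_loci),
            class = "combined_panel")
}

#' @export
print.combined_panel <- function(x, ...) {
  cat(sprintf("combined_panel: %d variants (%d GBS + %d anchor), %d evaluation loci\n",
              n_variants(x$matrix), sum(x$origin == "GBS"),
              sum(x$origin == "anchor"), nrow(x$evaluation_loci)))
  invisible(x)
}

#' k-nearest-neighbour haplotype-window imputation
#'
#' Fills every missing genotype call by local sample similarity. For a
#' missing call at locus `i`, other samples are ranked by genotype
#' agreement with the target over the non-missing markers both share
#' inside a window of `window` markers centered on `i` (at least
#' `min_overlap` comparable markers are required); the imputed genotype is
#' the unweighted majority genotype among the `k` best-ranked neighbours
#' with a non-missing call at the locus. If no neighbour qualifies, the
#' locus's major (most frequent observed) genotype is used; loci with no
#' observed call anywhere are left missing with a warning. Ties in
#' neighbour ranking are broken by sample order, ties in the majority vote
#' by genotype code order (`0/0` < `0/1` < `1/1`). The procedure is fully
#' deterministic given its inputs; `seed` is accepted for interface
#' symmetry with stochastic imputers.
#'
#' Originally observed calls are never altered.
#'
#' @param panel a [genotype_matrix()] (windows are taken in marker-index
#'   order of the panel, which [combine_panels()] position-sorts).
#' @param window window width in markers (odd, >= 3).
#' @param k number of neighbours (>= 1).
#' @param min_overlap minimum number of comparable markers for a
#'   neighbour to be ranked.
#' @param seed unused; present for interface compatibility.
#' @return an `imputation_result`: list with `matrix` (completed
#'   [genotype_matrix()]; DP/GQ of imputed calls are `NA`) and `imputed`
#'   (logical variants x samples mask of calls filled by imputation).
#' @export
impute_knn <- function(panel, window = 21L, k = 5L, min_overlap = 5L,
                       seed = NULL) {
  stopifnot(inherits(panel, "genotype_matrix"), window >= 3, k >= 1)
  gt <- panel$gt
  nv <- nrow(gt); ns <- ncol(gt)
  codes <- sort(unique(gt[!is.na(gt)]))
  gcode <- matrix(match(gt, codes), nv, ns)  # integer codes, NA = missing
  half <- window %/% 2L
  obs <- !is.na(gcode)
  imputed <- matrix(FALSE, nv, ns)
  out <- gcode
  # locus major genotype (fallback)
  major_at <- function(i) {
    tab <- tabulate(gcode[i, ], nbins = length(codes))
    if (all(tab == 0L)) NA_integer_ else which.max(tab)
  }
  for (i in seq_len(nv)) {
    miss <- which(!obs[i, ])
    if (length(miss) == 0L) next
    lo <- max(1L, i - half); hi <- min(nv, i + half)
    W <- gcode[lo:hi, , drop = FALSE]
    E <- obs[lo:hi, , drop = FALSE]
    major <- major_at(i)
    if (is.na(major)) {
      warning("locus ", panel$variants$chrom[i], ":", panel$variants$pos[i],
              " has no observed call; left missing", call. = FALSE)
      next
    }
    informative <- which(obs[i, ])
    # genotype agreement between every informative sample and every missing
    # sample over the window, via one-hot crossproducts
    Em <- E * 1
    match_all <- matrix(0, length(informative), length(miss))
    for (cc in seq_along(codes)) {
      Ic <- (W == cc) & E
      Ic <- Ic * 1
      match_all <- match_all +
        crossprod(Ic[, informative, drop = FALSE], Ic[, miss, drop = FALSE])
    }
    overlap_all <- crossprod(Em[, informative, drop = FALSE],
                             Em[, miss, drop = FALSE])
    for (j in seq_along(miss)) {
      s <- miss[j]
      overlap <- overlap_all[, j]
      eligible <- overlap >= min_overlap
      if (!any(eligible)) { out[i, s] <- major; imputed[i, s] <- TRUE; next }
      agree <- match_all[eligible, j] / overlap[eligible]
      cand <- informative[eligible]
      ord <- order(-agree, cand)        # ties: fixed sample order
      best <- cand[ord][seq_len(min(k, length(cand)))]
      votes <- tabulate(gcode[i, best], nbins = length(codes))
      out[i, s] <- which.max(votes)     # ties: lowest genotype code
      imputed[i, s] <- TRUE
    }
  }
  gt_out <- matrix(codes[out], nv, ns, dimnames = dimnames(gt))
  dimnames(imputed) <- dimnames(gt)
  dp <- panel$dp; gq <- panel$gq
  completed <- genotype_matrix(panel$samples, panel$variants, gt_out, dp, gq)
  structure(list(matrix = completed, imputed = imputed),
            class = "imputation_result")
}

#' Impute through an external program via VCF round-trip
#'
#' Writes the panel (with its missing calls) as VCF, substitutes the input
#' and output paths into `command` (`{in}` and `{out}` placeholders), runs
#' it with [system()], and reads the completed VCF back. The external
#' program must return a VCF with identical samples and variants and no
#' missing genotypes at the previously missing calls. Observed calls
#' altered by the program are restored to their original values so the
#' no-mutation guarantee holds for any imputer.
#'
#' @param panel a [genotype_matrix()].
#' @param command command template containing `{in}` and `{out}`.
#' @return an `imputation_result`, as for [impute_knn()].
#' @export
impute_external <- function(panel, command) {
  fin <- tempfile(fileext = ".vcf"); fout <- tempfile(fileext = ".vcf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_vcf(panel, fin)
  cmd <- gsub("{out}", fout, gsub("{in}", fin, command, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd)
  if (status != 0L) stop("external imputer failed with status ", status)
  done <- read_vcf(fout)
  key_p <- paste(panel$variants$chrom, panel$variants$pos,
                 panel$variants$ref, panel$variants$alt)
  key_d <- paste(done$variants$chrom, done$variants$pos,
                 done$variants$ref, done$variants$alt)
  idx <- match(key_p, key_d)
  if (anyNA(idx) || !setequal(panel$samples, done$samples))
    stop("external imputer changed the panel's variants or samples")
  gt <- done$gt[idx, match(panel$samples, done$samples), drop = FALSE]
  was_obs <- !is.na(panel$gt)
  gt[was_obs] <- panel$gt[was_obs]
  completed <- genotype_matrix(panel$samples, panel$variants, gt,
                               panel$dp, panel$gq)
  structure(list(matrix = completed, imputed = !was_obs & !is.na(gt)),
            class = "imputation_result")
}

#' Score imputed genotypes against a truth panel
#'
#' Computes concordance-based accuracy restricted to calls that were
#' actually imputed (originally missing) at the evaluation loci — the
#' variants shared with the unaltered truth panel. Originally observed
#' calls are excluded, so the statistic measures imputation quality alone.
#'
#' @param result an `imputation_result` from [impute_knn()] or
#'   [impute_external()].
#' @param truth the unaltered truth [genotype_matrix()].
#' @param evaluation_loci data.frame with `chrom` and `pos` columns
#'   (e.g. from [combine_panels()]); defaults to all loci shared with
#'   `truth`.
#' @return a `concordance_table` restricted to imputed calls; `NA`
#'   accuracy signals that no imputed call was scorable.
#' @export
evaluate_imputation <- function(result, truth, evaluation_loci = NULL) {
  stopifnot(inherits(result, "imputation_result"))
  m <- result$matrix
  mask <- result$imputed
  if (!is.null(evaluation_loci)) {
    key <- paste(m$variants$chrom, m$variants$pos)
    keep <- key %in% paste(evaluation_loci$chrom, evaluation_loci$pos)
    mask <- mask & keep
  }
  # hide non-imputed calls so the concordance counts imputed calls only
  m$gt[!mask] <- NA_character_
  m$dp[!mask] <- NA_real_
  m$gq[!mask] <- NA_real_
  keep_var <- rowSums(!is.na(m$gt)) > 0L
  if (!any(keep_var))
    return(concordance_table(c(0, 0, 0), c(0, 0, 0)))
  m <- subset_matrix(m, variants = keep_var)
  suppressMessages(concordance(m, truth))
}

#' Imputation accuracy across QC and panel-composition settings
#'
#' The synthetic analogue of a marker-combination design: for every
#' dataset in a QC grid, impute the GBS panel alone and (optionally) the
#' GBS panel merged with a dense anchor panel, and score the imputed
#' genotypes at the loci shared with the unaltered truth panel.
#'
#' @param grid a [dataset_grid()] result on the GBS matrix.
#' @param anchor dense-panel [genotype_matrix()], or `NULL` for GBS-only
#'   rows.
#' @param truth unaltered truth [genotype_matrix()].
#' @param combine logical vector of panel compositions to evaluate:
#'   `FALSE` = GBS only, `TRUE` = GBS + anchor.
#' @param imputer a function `f(panel)` returning an `imputation_result`
#'   (default [impute_knn()] with its defaults).
#' @param ... passed on to the imputer.
#' @return data.frame: grid configuration columns plus `combined`,
#'   `n_variants`, `n_eval_loci`, `n_imputed_scored`, `accuracy`.
#' @export
imputation_grid <- function(grid, anchor, truth, combine = c(FALSE, TRUE),
                            imputer = impute_knn, ...) {
  stopifnot(is.list(grid), !is.null(grid$datasets))
  if (is.null(anchor)) combine <- FALSE
  rows <- list()
  for (i in seq_along(grid$datasets)) {
    gbs <- grid$datasets[[i]]
    for (cmb in combine) {
      if (cmb) {
        cp <- combine_panels(gbs, anchor)
        panel <- cp$matrix
        eval_loci <- suppressMessages(shared_markers(gbs, truth))
        eval_loci <- gbs$variants[eval_loci$idx_a, c("chrom", "pos"),
                                  drop = FALSE]
      } else {
        panel <- gbs
        el <- suppressMessages(shared_markers(gbs, truth))
        eval_loci <- gbs$variants[el$idx_a, c("chrom", "pos"), drop = FALSE]
      }
      res <- imputer(panel, ...)
      ct <- evaluate_imputation(res, truth, eval_loci)
      rows[[length(rows) + 1L]] <-
        cbind(grid$table[i, , drop = FALSE],
              data.frame(combined = cmb, n_panel_variants = n_variants(panel),
                         n_eval_loci = nrow(eval_loci),
                         n_imputed_scored = ct$n_compared,
                         accuracy = ct$accuracy))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
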