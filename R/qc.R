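#' Quality-control configuration
#'
#' Thresholds of the two-step variant QC cascade. Step one acts on
#' individual calls (minimum read depth, minimum genotype quality); step
#' two acts on variants using statistics recomputed after step one
#' (call rate, minor allele frequency, number of alternative alleles,
#' monomorphism, chromosome exclusions, multi-nucleotide variants).
#'
#' The GQ threshold is applied as `GQ >= min_gq`. Call-rate and MAF
#' comparisons use `>=` on exact fractions, without pre-rounding; with a
#' 48-sample cohort, a minimum call rate of 0.2 therefore requires a
#' genotype in at least `ceiling(0.2 * 48) = 10` individuals.
#'
#' @param min_depth minimum read depth per call (integer >= 0).
#' @param min_gq minimum genotype quality per call, or `NULL` for no GQ
#'   filtering.
#' @param max_alt maximum number of alternative alleles per variant
#'   (default 1: biallelic only).
#' @param min_call_rate minimum per-variant call rate in `[0, 1]`.
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`.
#' @param exclude_chroms chromosome labels removed at the variant stage
#'   (default X, Y, MT: the non-autosomal exclusions).
#' @param drop_monomorphic drop variants with no observed minor allele.
#' @param drop_mnv drop multi-nucleotide variants (ref or any alt longer
#'   than 1 bp).
#' @return a `qc_config` object.
#' @export
qc_config <- function(min_depth = 0L, min_gq = NULL, max_alt = 1L,
                      min_call_rate = 0, min_maf = 0,
                      exclude_chroms = c("X", "Y", "MT"),
                      drop_monomorphic = FALSE, drop_mnv = FALSE) {
  stopifnot(min_depth >= 0, is.null(min_gq) || min_gq >= 0,
            max_alt >= 1, min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  structure(list(min_depth = as.integer(min_depth), min_gq = min_gq,
                 max_alt = as.integer(max_alt),
                 min_call_rate = min_call_rate, min_maf = min_maf,
                 exclude_chroms = as.character(exclude_chroms),
                 drop_monomorphic = isTRUE(drop_monomorphic),
                 drop_mnv = isTRUE(drop_mnv)),
            class = "qc_config")
}

#' Per-call filtering (QC step one)
#'
#' Sets to missing every non-missing call whose read depth is below
#' `min_depth` or, when `min_gq` is given, whose genotype quality is below
#' `min_gq` (the GQ filter keeps calls with `GQ >= min_gq`). Calls with
#' unknown (`NA`) depth or quality fail the corresponding threshold when it
#' is active: absence of evidence is treated conservatively. Variants left
#' with zero non-missing calls are dropped; variant identity is otherwise
#' preserved.
#'
#' @param x a [genotype_matrix()].
#' @param min_depth minimum read depth (0 disables).
#' @param min_gq minimum genotype quality, or `NULL` to skip GQ filtering.
#' @return a filtered [genotype_matrix()].
#' @export
filter_calls <- function(x, min_depth = 0, min_gq = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  gt <- x$gt; dp <- x$dp; gq <- x$gq
  bad <- matrix(FALSE, nrow(gt), ncol(gt))
  if (min_depth > 0) bad <- bad | is.na(dp) | dp < min_depth
  if (!is.null(min_gq)) bad <- bad | is.na(gq) | gq < min_gq
  bad <- bad & !is.na(gt)
  gt[bad] <- NA_character_
  dp[bad] <- NA_real_
  gq[bad] <- NA_real_
  keep <- rowSums(!is.na(gt)) > 0L
  genotype_matrix(x$samples, x$variants[keep, , drop = FALSE],
                  gt[keep, , drop = FALSE], dp[keep, , drop = FALSE],
                  gq[keep, , drop = FALSE])
}

#' Per-variant statistics
#'
#' Call rate (non-missing calls over all panel samples), minor allele
#' frequency (allele counts over non-missing calls only; the MAF is the
#' frequency of the second most common allele, so it always lies in
#' `[0, 0.5]`), alternative-allele count, monomorphism, and a
#' multi-nucleotide-variant flag. A variant with zero non-missing calls has
#' `NA` MAF and is flagged; it fails any MAF threshold.
#'
#' @param x a [genotype_matrix()].
#' @return data.frame with one row per variant: `chrom`, `pos`,
#'   `call_rate`, `maf`, `n_alt`, `monomorphic`, `mnv`.
#' @export
per_variant_stats <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"), n_samples(x) >= 1)
  gt <- x$gt
  nonmiss <- rowSums(!is.na(gt))
  cr <- nonmiss / ncol(gt)
  # vectorized fast path for rows coded purely biallelic (0/0, 0/1, 1/1)
  n01 <- rowSums(gt == "0/1", na.rm = TRUE)
  n11 <- rowSums(gt == "1/1", na.rm = TRUE)
  n00 <- rowSums(gt == "0/0", na.rm = TRUE)
  f_alt <- (n01 + 2 * n11) / (2 * nonmiss)
  maf <- pmin(f_alt, 1 - f_alt)
  mono <- f_alt == 0 | f_alt == 1
  maf[nonmiss == 0L] <- NA_real_
  mono[nonmiss == 0L] <- TRUE
  slow <- which(n00 + n01 + n11 < nonmiss)  # multi-allelic codes present
  for (i in slow) {
    g <- gt[i, ]
    alleles <- unlist(strsplit(g[!is.na(g)], "/", fixed = TRUE))
    freq <- sort(table(alleles), decreasing = TRUE) / length(alleles)
    maf[i] <- if (length(freq) > 1L) freq[[2L]] else 0
    mono[i] <- length(freq) == 1L
  }
  alts <- strsplit(x$variants$alt, ",", fixed = TRUE)
  data.frame(chrom = x$variants$chrom, pos = x$variants$pos,
             call_rate = cr, maf = maf,
             n_alt = lengths(alts),
             monomorphic = mono,
             mnv = nchar(x$variants$ref) > 1L |
                   vapply(alts, function(a) any(nchar(a) > 1L), logical(1)),
             stringsAsFactors = FALSE)
}

#' Per-variant filtering (QC step two)
#'
#' Retains variants whose call rate and MAF meet the configured minima
#' (`>=`, exact fractions), whose alternative-allele count does not exceed
#' `max_alt`, that are polymorphic (when `drop_monomorphic`), that are not
#' multi-nucleotide variants (when `drop_mnv`), and whose chromosome is not
#' excluded. Call-level thresholds in `config` are applied first, so the
#' function runs the full cascade in the documented order: calls first,
#' then variant statistics recomputed on the filtered calls. Deterministic
#' and order-preserving.
#'
#' @param x a [genotype_matrix()].
#' @param config a [qc_config()].
#' @return a filtered [genotype_matrix()].
#' @export
filter_variants <- function(x, config) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(config, "qc_config"))
  x <- filter_calls(x, config$min_depth, config$min_gq)
  if (n_variants(x) == 0L) return(x)
  st <- per_variant_stats(x)
  keep <- st$call_rate >= config$min_call_rate &
          !is.na(st$maf) & st$maf >= config$min_maf &
          st$n_alt <= config$max_alt &
          !(st$chrom %in% config$exclude_chroms)
  if (config$drop_monomorphic) keep <- keep & !st$monomorphic
  if (config$drop_mnv) keep <- keep & !st$mnv
  subset_matrix(x, variants = keep)
}

#' Derive a grid of QC'd datasets
#'
#' Applies every combination of the supplied threshold levels to the raw
#' matrix, each derived dataset recomputed independently from `x`. The
#' returned table mirrors the usual QC-report layout: one row per
#' configuration with the retained variant and non-missing call counts.
#'
#' @param x a raw [genotype_matrix()].
#' @param depth_levels integer vector of minimum read depths.
#' @param gq_levels list of minimum GQ values; use `NA` (or `NULL` entries)
#'   for "no GQ filter".
#' @param call_rate_levels,maf_levels numeric vectors (default 0: off).
#' @param ... further arguments passed to [qc_config()] (e.g.
#'   `drop_monomorphic`, `exclude_chroms`).
#' @return list with `table` (data.frame: `min_depth`, `min_gq`,
#'   `min_call_rate`, `min_maf`, `n_variants`, `n_calls`) and `datasets`
#'   (list of [genotype_matrix()], one per row).
#' @export
dataset_grid <- function(x, depth_levels = c(3L, 4L, 5L, 6L),
                         gq_levels = list(NA, 20), call_rate_levels = 0,
                         maf_levels = 0, ...) {
  stopifnot(length(depth_levels) >= 1, length(gq_levels) >= 1,
            length(call_rate_levels) >= 1, length(maf_levels) >= 1)
  gq_levels <- lapply(gq_levels, function(g)
    if (is.null(g) || (length(g) == 1L && is.na(g))) NULL else g)
  combos <- expand.grid(d = seq_along(depth_levels),
                        g = seq_along(gq_levels),
                        c = seq_along(call_rate_levels),
                        m = seq_along(maf_levels))
  datasets <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    gq <- gq_levels[[combos$g[i]]]
    cfg <- qc_config(min_depth = depth_levels[combos$d[i]], min_gq = gq,
                     min_call_rate = call_rate_levels[combos$c[i]],
                     min_maf = maf_levels[combos$m[i]], ...)
    ds <- filter_variants(x, cfg)
    datasets[[i]] <- ds
    rows[[i]] <- data.frame(min_depth = cfg$min_depth,
                            min_gq = if (is.null(gq)) NA_real_ else gq,
                            min_call_rate = cfg$min_call_rate,
                            min_maf = cfg$min_maf,
                            n_variants = n_variants(ds),
                            n_calls = sum(!is.na(ds$gt)))
  }
  list(table = do.call(rbind, rows), datasets = datasets)
}
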