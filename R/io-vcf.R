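#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and returns the package's
#' `genotype_matrix` container. GT is required in FORMAT; DP and GQ are
#' optional. When DP or GQ is absent from the file's FORMAT entirely, the
#' corresponding layer defaults to 0 for non-missing calls and a warning is
#' issued (calls without depth/quality evidence are treated conservatively
#' by downstream filters). Per-call `"."` values become `NA`.
#'
#' Coordinates are 1-based, following the VCF convention. Phase separators
#' (`|`) are accepted but phase is never interpreted; genotypes are stored
#' unphased with allele indices sorted.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"],
                         alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  bad <- which(is.na(variants$pos))
  if (length(bad))
    stop("malformed VCF record (unparsable POS) at data line ", bad[1],
         " of ", path)
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key))
    stop("duplicated variant (chrom,pos,ref,alt) in ", path, ": ",
         key[duplicated(key)][1])
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)
  fmt <- unique(v@gt[, "FORMAT"])
  keys <- unique(unlist(strsplit(fmt, ":", fixed = TRUE)))
  if (!"GT" %in% keys) stop("VCF FORMAT lacks GT: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  has_gt <- !is.na(normalize_gt(gt))
  grab <- function(key) {
    if (key %in% keys) {
      m <- suppressWarnings(vcfR::extract.gt(v, element = key, as.numeric = TRUE))
      matrix(as.numeric(m), nrow = nrow(gt))
    } else {
      warning("FORMAT field ", key, " absent from ", path,
              "; defaulting to 0 for non-missing calls", call. = FALSE)
      out <- matrix(NA_real_, nrow(gt), ncol(gt))
      out[has_gt] <- 0
      out
    }
  }
  dp <- grab("DP")
  gq <- grab("GQ")
  genotype_matrix(colnames(gt), variants, gt, dp, gq)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a minimal VCF 4.2 with FORMAT `GT:DP:GQ`, variants sorted by
#' (chromosome, position). Missing genotypes are written as `"./."`; missing
#' DP/GQ values as `"."`. `read_vcf(write_vcf(m))` reproduces `m` exactly
#' (up to the canonical variant sort order).
#'
#' @param x a [genotype_matrix()]; must contain at least one variant.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (n_variants(x) == 0L) stop("cannot write an empty genotype matrix")
  ord <- order(x$variants$chrom, x$variants$pos)
  v <- x$variants[ord, , drop = FALSE]
  gt <- x$gt[ord, , drop = FALSE]
  dp <- x$dp[ord, , drop = FALSE]
  gq <- x$gq[ord, , drop = FALSE]
  fmt_num <- function(m) {
    out <- matrix(".", nrow(m), ncol(m))
    ok <- !is.na(m)
    out[ok] <- format(m[ok], trim = TRUE, scientific = FALSE, digits = 15)
    out
  }
  gt_chr <- gt
  gt_chr[is.na(gt_chr)] <- "./."
  cells <- matrix(paste(gt_chr, fmt_num(dp), fmt_num(gq), sep = ":"),
                  nrow(gt), ncol(gt))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                "GT:DP:GQ",
                apply(cells, 1L, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gbskit",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality (phred)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read bedGraph coverage into dense per-base depth vectors
#'
#' Reads 4-column bedGraph records (chrom, start, end, depth; 0-based
#' half-open intervals) and expands them into one dense numeric vector per
#' chromosome. Bases not covered by any record have depth 0. The vector
#' length is the largest end coordinate seen per chromosome unless
#' `chrom_lengths` supplies a longer known length.
#'
#' @param path path to a bedGraph file (no track lines).
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return named list of numeric depth vectors, one per chromosome.
#' @export
read_coverage <- function(path, chrom_lengths = NULL) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      col.names = c("chrom", "start", "end", "depth"),
                      colClasses = c("character", "integer", "integer", "numeric")),
    error = function(e) {
      # an empty file is legitimate all-zero coverage
      if (file.size(path) == 0)
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), depth = numeric(0)))
      stop("failed to parse bedGraph '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (any(df$depth < 0)) stop("negative depth in ", path)
  if (any(df$end <= df$start)) stop("empty or inverted interval in ", path)
  out <- list()
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping coverage intervals on ", chrom, " in ", path)
    len <- max(d$end, chrom_lengths[chrom], na.rm = TRUE)
    vec <- numeric(len)
    for (i in seq_len(nrow(d)))
      vec[(d$start[i] + 1L):d$end[i]] <- d$depth[i]
    out[[chrom]] <- vec
  }
  if (!is.null(chrom_lengths)) {
    for (chrom in setdiff(names(chrom_lengths), names(out)))
      out[[chrom]] <- numeric(chrom_lengths[[chrom]])
  }
  out
}
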