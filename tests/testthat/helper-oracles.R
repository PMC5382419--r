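# Independent oracles and small fixture builders shared across tests.

# Brute-force IUPAC site scan: tests every offset of seq against the site
# using an explicit code table; deliberately independent of Biostrings.
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

brute_force_cuts <- function(seq, enzyme) {
  seq <- toupper(seq)
  site <- strsplit(enzyme$site, "")[[1]]
  chars <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  for (start in seq_len(nchar(seq) - length(site) + 1L)) {
    ok <- TRUE
    for (j in seq_along(site)) {
      base <- chars[start + j - 1L]
      # an ambiguous base in the sequence (e.g. N) never matches
      if (!base %in% c("A", "C", "G", "T") ||
          !base %in% IUPAC_SETS[[site[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, start - 1L + enzyme$cut_offset)
  }
  sort(unique(hits))
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# Naive per-variant QC oracle: recomputes the full cascade one variant at
# a time with scalar logic, independent of the vectorized implementation.
brute_force_qc <- function(x, cfg) {
  keep <- logical(n_variants(x))
  for (i in seq_len(n_variants(x))) {
    gt <- x$gt[i, ]; dp <- x$dp[i, ]; gq <- x$gq[i, ]
    for (s in seq_along(gt)) {
      if (is.na(gt[s])) next
      if (cfg$min_depth > 0 && (is.na(dp[s]) || dp[s] < cfg$min_depth))
        gt[s] <- NA
      else if (!is.null(cfg$min_gq) && (is.na(gq[s]) || gq[s] < cfg$min_gq))
        gt[s] <- NA
    }
    known <- gt[!is.na(gt)]
    if (length(known) == 0L) { keep[i] <- FALSE; next }
    alleles <- unlist(strsplit(known, "/"))
    tab <- sort(table(alleles), decreasing = TRUE)
    freq <- tab / sum(tab)
    maf <- if (length(freq) > 1) freq[[2]] else 0
    keep[i] <-
      (length(known) / length(gt)) >= cfg$min_call_rate &&
      maf >= cfg$min_maf &&
      length(strsplit(x$variants$alt[i], ",")[[1]]) <= cfg$max_alt &&
      !(x$variants$chrom[i] %in% cfg$exclude_chroms) &&
      (!cfg$drop_monomorphic || length(freq) > 1) &&
      (!cfg$drop_mnv ||
         (nchar(x$variants$ref[i]) == 1 &&
          all(nchar(strsplit(x$variants$alt[i], ",")[[1]]) == 1)))
  }
  keep
}

# Hand-built small genotype matrix
toy_matrix <- function() {
  genotype_matrix(
    samples = c("A", "B"),
    variants = data.frame(chrom = c("1", "1", "2"),
                          pos = c(100L, 200L, 50L),
                          ref = c("A", "C", "G"),
                          alt = c("G", "T", "A")),
    gt = matrix(c("0/0", "0/1",
                  "1/1", NA,
                  "0/1", "0/0"), nrow = 3, byrow = TRUE),
    dp = matrix(c(5, 3, 8, NA, 2, 10), nrow = 3, byrow = TRUE),
    gq = matrix(c(30, 20, 99, NA, 7, 45), nrow = 3, byrow = TRUE))
}

# An all-heterozygous single-site-type truth for depth experiments
all_het_truth <- function(n_samples, n_sites) {
  population_truth(sprintf("S%03d", seq_len(n_samples)),
                   data.frame(chrom = "1", pos = seq_len(n_sites) * 10L,
                              ref = "A", alt = "C", maf = 0.5),
                   matrix(1L, n_sites, n_samples))
}
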