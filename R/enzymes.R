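#' Restriction enzyme specification
#'
#' A recognition site as an IUPAC DNA string together with the top-strand
#' cut offset: the cut falls `cut_offset` bases after the start of a site
#' match, so PstI (CTGCA^G) has offset 5 and MspI (C^CGG) offset 1.
#'
#' Cut positions are computed on the top strand only. For the palindromic
#' sites bundled here this loses nothing; ApeKI's degenerate site GCWGC is
#' its own reverse complement as an IUPAC set, so forward matching already
#' finds every site.
#'
#' @param name enzyme label.
#' @param site IUPAC DNA recognition sequence.
#' @param cut_offset integer in `[0, nchar(site)]`.
#' @return an `enzyme_spec` object.
#' @examples
#' enzyme_spec("PstI", "CTGCAG", 5)
#' @export
enzyme_spec <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (!nzchar(site) || grepl("[^ACGTRYSWKMBDHVN]", site))
    stop("invalid IUPAC recognition site: ", site)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site))
    stop("cut offset must lie within [0, site length]")
  structure(list(name = as.character(name), site = site,
                 cut_offset = cut_offset),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("%s: %s^%s\n", x$name,
              substr(x$site, 1, x$cut_offset),
              substr(x$site, x$cut_offset + 1, nchar(x$site))))
  invisible(x)
}

#' Built-in restriction enzymes
#'
#' PstI (CTGCA^G), MspI (C^CGG) and ApeKI (G^CWGC) — the rare, frequent and
#' degenerate cutters commonly used in two-enzyme and single-enzyme GBS
#' protocols.
#'
#' @param name enzyme name (case-insensitive).
#' @return an [enzyme_spec()].
#' @export
gbs_enzyme <- function(name) {
  table <- list(psti = enzyme_spec("PstI", "CTGCAG", 5L),
                mspi = enzyme_spec("MspI", "CCGG", 1L),
                apeki = enzyme_spec("ApeKI", "GCWGC", 1L))
  key <- tolower(name)
  if (!key %in% names(table)) stop("unknown built-in enzyme: ", name)
  table[[key]]
}

#' Locate restriction cut sites on a sequence
#'
#' Finds every top-strand occurrence of the enzyme's recognition site
#' (IUPAC codes in the site are expanded; `N` in the sequence never matches
#' any site letter) and returns the 0-based cut positions
#' `match_start + cut_offset`, sorted and deduplicated. Overlapping site
#' occurrences each contribute a cut.
#'
#' @param seq a DNA string (character or `Biostrings::DNAString`).
#' @param enzyme an [enzyme_spec()].
#' @return sorted integer vector of 0-based cut positions.
#' @export
find_cut_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  m <- Biostrings::matchPattern(Biostrings::DNAString(enzyme$site), seq,
                                fixed = "subject")
  sort(unique(Biostrings::start(m) - 1L + enzyme$cut_offset))
}

#' In-silico restriction digestion
#'
#' Digests each sequence with one or two enzymes: cut positions from all
#' enzymes are merged per chromosome and, together with the chromosome ends,
#' delimit fragments that tile the chromosome exactly. Each fragment end is
#' labeled with the enzyme that produced its bounding cut, or
#' `"chromosome-end"`. When two enzymes cut at the same position, the label
#' of the first enzyme in `enzymes` is kept.
#'
#' @param seqs named character vector or `DNAStringSet` of sequences.
#' @param enzymes a list of one or two [enzyme_spec()] objects (a single
#'   spec is accepted).
#' @return a `fragment_set`: list with `fragments` (data.frame `chrom`,
#'   `start`, `end` 0-based half-open, `left_end`, `right_end`, `length`)
#'   and `enzymes`.
#' @export
digest <- function(seqs, enzymes) {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  if (length(enzymes) < 1L || length(enzymes) > 2L)
    stop("digestion takes 1 or 2 enzymes")
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  if (length(seqs) == 0L) stop("empty sequence set")
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    len <- length(s)
    cuts <- integer(0); labels <- character(0)
    for (enz in enzymes) {
      cc <- find_cut_sites(s, enz)
      new <- !(cc %in% cuts)
      cuts <- c(cuts, cc[new])
      labels <- c(labels, rep(enz$name, sum(new)))
    }
    ord <- order(cuts)
    cuts <- cuts[ord]; labels <- labels[ord]
    inner <- cuts > 0L & cuts < len
    cuts <- cuts[inner]; labels <- labels[inner]
    bounds <- c(0L, cuts, len)
    ends <- c("chromosome-end", labels, "chromosome-end")
    rows[[i]] <- data.frame(
      chrom = names(seqs)[i],
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      left_end = ends[-length(ends)],
      right_end = ends[-1L],
      stringsAsFactors = FALSE)
  }
  fragments <- do.call(rbind, rows)
  fragments$length <- fragments$end - fragments$start
  structure(list(fragments = fragments, enzymes = enzymes),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragments on %d sequence(s), enzymes: %s\n",
              nrow(x$fragments), length(unique(x$fragments$chrom)),
              paste(vapply(x$enzymes, `[[`, "", "name"), collapse = "+")))
  invisible(x)
}

#' Fragment-size histogram
#'
#' Bins fragment lengths at a fixed bin width and reports per-bin counts
#' and percentages of the total fragment count, plus the number of
#' fragments whose length falls in a summary window (default 100-500 bp
#' inclusive, the size range efficiently sequenced on short-read
#' instruments).
#'
#' @param frags a `fragment_set` from [digest()].
#' @param bin_width bin width in bp (> 0); default 100.
#' @param max_size lengths above this are pooled into a final open-ended
#'   bin; default 2000.
#' @param window length-2 numeric, inclusive window for the summary count.
#' @return list with `table` (data.frame `bin_start`, `bin_end`, `count`,
#'   `percent`), `window_count` and `total`.
#' @export
size_histogram <- function(frags, bin_width = 100, max_size = 2000,
                           window = c(100, 500)) {
  stopifnot(inherits(frags, "fragment_set"), bin_width > 0)
  len <- frags$fragments$length
  breaks <- seq(0, max_size, by = bin_width)
  idx <- pmin(len %/% bin_width, length(breaks) - 1L) + 1L
  count <- tabulate(idx, nbins = length(breaks))
  tab <- data.frame(bin_start = breaks,
                    bin_end = c(breaks[-1L], Inf),
                    count = count,
                    percent = 100 * count / length(len))
  list(table = tab,
       window_count = sum(len >= window[1] & len <= window[2]),
       total = length(len))
}

#' Select GBS-sequenceable fragments from a double digestion
#'
#' In a two-enzyme GBS library only fragments with one rare-cutter end and
#' one common-cutter end (either orientation) receive both adapters and can
#' be amplified and sequenced; rare-rare, common-common and chromosome-end
#' fragments are excluded.
#'
#' @param frags a `fragment_set` from a two-enzyme [digest()].
#' @param rare,common enzyme names present in the digestion.
#' @return a `fragment_set` containing only the sequenceable fragments.
#' @export
sequenceable_fragments <- function(frags, rare, common) {
  stopifnot(inherits(frags, "fragment_set"))
  if (length(frags$enzymes) != 2L)
    stop("sequenceable fragments are defined for double digestions only")
  used <- vapply(frags$enzymes, `[[`, "", "name")
  if (!all(c(rare, common) %in% used))
    stop("rare/common enzyme not among the digestion's enzymes: ",
         paste(setdiff(c(rare, common), used), collapse = ", "))
  f <- frags$fragments
  keep <- (f$left_end == rare & f$right_end == common) |
          (f$left_end == common & f$right_end == rare)
  structure(list(fragments = f[keep, , drop = FALSE], enzymes = frags$enzymes),
            class = "fragment_set")
}

#' Write fragments as BED6
#'
#' 0-based half-open intervals; the name column carries the end-type pair
#' (e.g. `"PstI-MspI"`), score is the fragment length, strand `"."`.
#'
#' @param frags a `fragment_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  f <- frags$fragments
  lines <- paste(f$chrom, f$start, f$end,
                 paste0(f$left_end, "-", f$right_end),
                 f$length, ".", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Count fragments from per-base coverage
#'
#' Estimates the number of sequenced fragments per chromosome as the number
#' of maximal runs of strictly positive depth, assuming distinct fragments
#' are separated by stretches of zero coverage.
#'
#' @param depths named list of per-base depth vectors, as returned by
#'   [read_coverage()].
#' @return named integer vector of fragment counts per chromosome.
#' @export
fragments_from_coverage <- function(depths) {
  vapply(depths, function(v) {
    pos <- v > 0
    sum(pos & !c(FALSE, pos[-length(pos)]))
  }, integer(1))
}

#' Aggregate per-sample fragment counts
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of
#' per-chromosome fragment counts across samples. With a single sample the
#' standard deviation is `NA`.
#'
#' @param counts a list with one element per sample, each a named numeric
#'   vector of per-chromosome fragment counts (chromosome sets must agree).
#' @return data.frame with columns `chrom`, `mean`, `sd`, `n_samples`.
#' @export
aggregate_fragment_estimate <- function(counts) {
  if (length(counts) == 0L) stop("no samples supplied")
  chroms <- names(counts[[1]])
  m <- vapply(counts, function(x) as.numeric(x[chroms]), numeric(length(chroms)))
  m <- matrix(m, nrow = length(chroms))
  if (anyNA(m)) stop("chromosome sets differ between samples")
  data.frame(chrom = chroms,
             mean = rowMeans(m),
             sd = apply(m, 1L, stats::sd),
             n_samples = length(counts),
             stringsAsFactors = FALSE)
}
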