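#' Population truth for simulation
#'
#' Holds the error-free diploid genotypes of a synthetic cohort: sample
#' ids, variant sites with their generating minor allele frequency, and a
#' sites x samples matrix of true alt-allele dosages (0, 1, 2). Produced by
#' [simulate_truth()] (independent sites under Hardy-Weinberg equilibrium)
#' or [simulate_block_truth()] (haplotype-block linkage structure).
#'
#' @param samples character sample ids.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`, `maf`.
#' @param geno integer matrix (sites x samples) of dosages in `{0, 1, 2}`.
#' @param blocks optional haplotype-block bookkeeping (see
#'   [simulate_block_truth()]).
#' @return a `population_truth` object.
#' @export
population_truth <- function(samples, sites, geno, blocks = NULL) {
  samples <- as.character(samples)
  geno <- matrix(as.integer(geno), nrow = nrow(sites), ncol = length(samples))
  stopifnot(all(geno %in% 0:2))
  structure(list(samples = samples, sites = sites, geno = geno,
                 blocks = blocks),
            class = "population_truth")
}

#' @export
print.population_truth <- function(x, ...) {
  cat(sprintf("population_truth: %d sites x %d samples%s\n",
              nrow(x$sites), length(x$samples),
              if (is.null(x$blocks)) " (independent sites)"
              else sprintf(" (%d haplotype blocks, %d founders)",
                           max(x$blocks$block_of_site), x$blocks$n_founders)))
  invisible(x)
}

draw_maf <- function(maf_dist, n) {
  if (!is.function(maf_dist)) {
    if (length(maf_dist) != 2L || maf_dist[1] <= 0 || maf_dist[2] > 0.5 ||
        maf_dist[1] > maf_dist[2])
      stop("maf_dist range must satisfy 0 < lower <= upper <= 0.5")
  }
  q <- if (is.function(maf_dist)) maf_dist(n)
       else stats::runif(n, maf_dist[1], maf_dist[2])
  if (any(q <= 0) || any(q > 0.5))
    stop("minor allele frequencies must lie in (0, 0.5]")
  q
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

make_sites <- function(n_sites, chrom, spacing, maf) {
  al <- random_alleles(n_sites)
  data.frame(chrom = chrom, pos = spacing * seq_len(n_sites),
             ref = al$ref, alt = al$alt, maf = maf,
             stringsAsFactors = FALSE)
}

#' Simulate an independent-site diploid population
#'
#' Draws a minor allele frequency per site from `maf_dist`, then sample
#' genotypes i.i.d. under Hardy-Weinberg equilibrium:
#' `P(MM) = (1-q)^2`, `P(Mm) = 2q(1-q)`, `P(mm) = q^2`.
#'
#' @param n_samples,n_sites cohort dimensions (>= 1).
#' @param maf_dist either a length-2 numeric range for a uniform MAF
#'   spectrum (default `c(0.05, 0.5)`) or a function `f(n)` returning `n`
#'   frequencies in `(0, 0.5]`.
#' @param chrom chromosome label for all sites.
#' @param spacing distance in bp between consecutive sites.
#' @param seed optional integer seed; identical seeds give identical truth.
#' @return a [population_truth()].
#' @export
simulate_truth <- function(n_samples, n_sites, maf_dist = c(0.05, 0.5),
                           chrom = "1", spacing = 1000L, seed = NULL) {
  stopifnot(n_samples >= 1, n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  q <- draw_maf(maf_dist, n_sites)
  geno <- matrix(stats::rbinom(n_sites * n_samples, 2L, rep(q, n_samples)),
                 nrow = n_sites)
  population_truth(sprintf("S%03d", seq_len(n_samples)),
                   make_sites(n_sites, chrom, spacing, q), geno)
}

#' Simulate a diploid population with haplotype-block linkage
#'
#' Sites are grouped into consecutive blocks of `block_length` markers.
#' Each block carries `n_founders` founder haplotypes whose alleles are
#' drawn per site as Bernoulli(q); each sample draws two founder haplotypes
#' per block uniformly at random. Within a block, nearby markers therefore
#' share the founder mosaic — the linkage disequilibrium a
#' population-based imputer exploits. Across blocks haplotypes are drawn
#' independently, so LD does not extend past block boundaries.
#'
#' @inheritParams simulate_truth
#' @param block_length markers per haplotype block (default 100: at the
#'   default 1 kb spacing a 100 kb block, the scale over which linkage
#'   disequilibrium persists in cattle-like populations).
#' @param n_founders founder haplotypes per block (default 8).
#' @return a [population_truth()] whose `blocks` element records
#'   `block_of_site`, the per-block founder assignments `hap1`/`hap2`
#'   (samples x blocks) and `n_founders` — enough to generate additional
#'   in-LD markers later (see [simulate_array_panel()]).
#' @export
simulate_block_truth <- function(n_samples, n_sites,
                                 maf_dist = c(0.05, 0.5),
                                 block_length = 100L, n_founders = 8L,
                                 chrom = "1", spacing = 1000L, seed = NULL) {
  stopifnot(n_samples >= 1, n_sites >= 1, block_length >= 1, n_founders >= 2)
  if (!is.null(seed)) set.seed(seed)
  block_of_site <- (seq_len(n_sites) - 1L) %/% block_length + 1L
  n_blocks <- max(block_of_site)
  q <- draw_maf(maf_dist, n_sites)
  # founder alleles: n_founders x n_sites, Bernoulli(q) per site
  founder <- matrix(stats::rbinom(n_founders * n_sites, 1L,
                                  rep(q, each = n_founders)),
                    nrow = n_founders)
  hap1 <- matrix(sample.int(n_founders, n_samples * n_blocks, replace = TRUE),
                 nrow = n_samples)
  hap2 <- matrix(sample.int(n_founders, n_samples * n_blocks, replace = TRUE),
                 nrow = n_samples)
  geno <- matrix(0L, n_sites, n_samples)
  for (s in seq_len(n_samples)) {
    b <- block_of_site
    geno[, s] <- founder[cbind(hap1[s, b], seq_len(n_sites))] +
                 founder[cbind(hap2[s, b], seq_len(n_sites))]
  }
  population_truth(sprintf("S%03d", seq_len(n_samples)),
                   make_sites(n_sites, chrom, spacing, q), geno,
                   blocks = list(block_of_site = block_of_site,
                                 hap1 = hap1, hap2 = hap2,
                                 n_founders = n_founders))
}

#' Subset a population truth by site index
#'
#' @param truth a [population_truth()].
#' @param sites integer or logical site index.
#' @return a [population_truth()] restricted to the selected sites.
#' @export
subset_truth <- function(truth, sites) {
  idx <- if (is.logical(sites)) which(sites) else as.integer(sites)
  blocks <- truth$blocks
  if (!is.null(blocks)) blocks$block_of_site <- blocks$block_of_site[idx]
  population_truth(truth$samples, truth$sites[idx, , drop = FALSE],
                   truth$geno[idx, , drop = FALSE], blocks)
}

dosage_to_gt <- function(d) c("0/0", "0/1", "1/1")[d + 1L]

#' Expose a population truth as an error-free genotype matrix
#'
#' All calls present; DP and GQ are `NA` (not applicable to an assumed
#' error-free source).
#'
#' @param truth a [population_truth()].
#' @return a [genotype_matrix()].
#' @export
truth_as_matrix <- function(truth) {
  gt <- matrix(dosage_to_gt(truth$geno), nrow = nrow(truth$sites))
  genotype_matrix(truth$samples, truth$sites[, c("chrom", "pos", "ref", "alt")],
                  gt)
}

#' Read-depth model for GBS calls
#'
#' Per sample x site, depth is 0 (a missing call) with probability
#' `zero_mass` — restriction-site polymorphism, methylation or library
#' dropout — and otherwise drawn from the chosen family. The negative
#' binomial (`rnbinom` with `mu = mean_depth * f_site`, `size =
#' dispersion`) gives the long right tail with most calls under 10 reads
#' that low-coverage GBS shows. `f_site` is a per-site coverage multiplier
#' drawn once per site from a mean-1 gamma with shape `site_shape`: the
#' same restriction fragment tends to amplify well (or poorly) in every
#' sample, which spreads per-variant call rates widely instead of
#' concentrating them at the cohort average — the feature that makes
#' call-rate thresholds meaningful. `site_shape = Inf` disables the site
#' effect; `"fixed"` forces a constant depth, convenient for studying the
#' caller at a single depth.
#'
#' Defaults (mean 4, dispersion 1, site shape 1, zero mass 0.47) put the
#' average per-sample call rate near 0.35, typical of a low-coverage
#' two-enzyme GBS assay.
#'
#' @param family `"nbinom"` or `"fixed"`.
#' @param mean_depth mean of the non-zero-inflated component (> 0).
#' @param dispersion negative-binomial size parameter.
#' @param zero_mass extra probability of a zero-read (missing) call.
#' @param site_shape gamma shape of the per-site coverage multiplier;
#'   `Inf` for homogeneous sites.
#' @return a `depth_model` object.
#' @export
depth_model <- function(family = c("nbinom", "fixed"), mean_depth = 4,
                        dispersion = 1, zero_mass = 0.47, site_shape = 1) {
  family <- match.arg(family)
  stopifnot(mean_depth > 0, dispersion > 0,
            zero_mass >= 0, zero_mass <= 1, site_shape > 0)
  structure(list(family = family, mean_depth = mean_depth,
                 dispersion = dispersion, zero_mass = zero_mass,
                 site_shape = site_shape),
            class = "depth_model")
}

#' Artifact model: allele dropout and sequencing error
#'
#' `dropout` is the probability that, at a heterozygous sample x site, one
#' allele (chosen at random) is entirely unamplified, so every read comes
#' from the other chromosome — the selective-primer artifact that converts
#' true heterozygotes into confident homozygotes. `error_rate` is the
#' per-read probability of reporting the other allele.
#'
#' @param dropout probability in `[0, 1]` (default 0).
#' @param error_rate per-read error probability in `[0, 1]` (default 0.01,
#'   a typical short-read substitution rate).
#' @return an `artifact_model` object.
#' @export
artifact_model <- function(dropout = 0, error_rate = 0.01) {
  stopifnot(dropout >= 0, dropout <= 1, error_rate >= 0, error_rate <= 1)
  structure(list(dropout = dropout, error_rate = error_rate),
            class = "artifact_model")
}

# x*log(p) with the 0*log(0) = 0 convention
xlogp <- function(x, p) ifelse(x == 0L, 0, x * log(p))

#' Simulate GBS genotype calls from a population truth
#'
#' For each sample x site: draw a read depth from `depth` (0 reads gives a
#' missing call); each read samples one of the two chromosomes uniformly
#' (or only the retained chromosome under allele dropout) and is miscopied
#' with probability `artifact$error_rate`; the genotype is then called by
#' maximum posterior under the three-genotype read likelihood with a flat
#' prior — per read, `P(read | hom) = 1 - eps` (matching allele) or `eps`,
#' and `P(read | het) = 1/2`. Ties are broken toward the heterozygote, then
#' toward hom-ref. GQ is `-10 log10(1 - posterior of the called genotype)`,
#' rounded to an integer and capped at 99; DP is the read count.
#'
#' @param truth a [population_truth()].
#' @param depth a [depth_model()].
#' @param artifact an [artifact_model()].
#' @param seed optional integer seed.
#' @return a [genotype_matrix()] with GT/DP/GQ layers.
#' @export
simulate_gbs_calls <- function(truth, depth = depth_model(),
                               artifact = artifact_model(), seed = NULL) {
  stopifnot(inherits(truth, "population_truth"),
            inherits(depth, "depth_model"),
            inherits(artifact, "artifact_model"))
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(truth$sites); ns <- length(truth$samples)
  n <- nv * ns
  d <- switch(depth$family,
              nbinom = {
                f <- if (is.finite(depth$site_shape))
                  stats::rgamma(nv, shape = depth$site_shape,
                                rate = depth$site_shape)
                else rep(1, nv)
                stats::rnbinom(n, size = depth$dispersion,
                               mu = depth$mean_depth * rep(f, ns))
              },
              fixed = rep(as.integer(round(depth$mean_depth)), n))
  d[stats::runif(n) < depth$zero_mass] <- 0L
  g <- as.vector(truth$geno)
  eps <- artifact$error_rate
  # per-entry probability that a read reports the alt allele
  p_alt <- ifelse(g == 0L, eps, ifelse(g == 2L, 1 - eps, 0.5))
  if (artifact$dropout > 0) {
    het <- which(g == 1L)
    drop <- het[stats::runif(length(het)) < artifact$dropout]
    retained_alt <- stats::runif(length(drop)) < 0.5
    p_alt[drop] <- ifelse(retained_alt, 1 - eps, eps)
  }
  nalt <- stats::rbinom(n, d, p_alt)
  nref <- d - nalt
  # flat-prior three-genotype posterior from the read counts
  lmm <- xlogp(nref, 1 - eps) + xlogp(nalt, eps)      # hom-ref
  lhet <- -d * log(2)                                  # het
  laa <- xlogp(nref, eps) + xlogp(nalt, 1 - eps)       # hom-alt
  ll <- cbind(lhet, lmm, laa)  # tie preference: het, then hom-ref
  best <- max.col(ll, ties.method = "first")
  mx <- ll[cbind(seq_len(n), best)]
  denom <- exp(lhet - mx) + exp(lmm - mx) + exp(laa - mx)
  post <- 1 / denom
  call_dosage <- c(1L, 0L, 2L)[best]
  gq <- -10 * log10(pmax(1 - post, 0))
  gq <- pmin(round(gq), 99)
  gt <- dosage_to_gt(call_dosage)
  miss <- d == 0L
  gt[miss] <- NA_character_
  dp <- as.numeric(d); dp[miss] <- NA_real_
  gq[miss] <- NA_real_
  genotype_matrix(truth$samples,
                  truth$sites[, c("chrom", "pos", "ref", "alt")],
                  matrix(gt, nv, ns), matrix(dp, nv, ns), matrix(gq, nv, ns))
}

#' Simulate a dense array panel overlapping a population truth
#'
#' Builds an independent genotyping-array-style panel: a seeded random
#' subset of the truth's sites (fraction `overlap_fraction`, count rounded)
#' plus `n_extra` additional markers placed midway between existing sites.
#' Extra markers on a block-structured truth are generated on the same
#' founder haplotypes as their flanking sites, so they are in linkage
#' disequilibrium with the truth's markers; on an independent-site truth
#' they are i.i.d. Hardy-Weinberg draws. Genotypes are copied from the
#' (extended) truth; with probability `error_rate` a call is replaced by
#' one of the two other genotype classes (default 0: an error-free panel).
#'
#' @param truth a [population_truth()].
#' @param overlap_fraction fraction of truth sites included in the panel.
#' @param n_extra number of additional dense markers (at most
#'   `n_sites - 1`, one per inter-site gap).
#' @param error_rate per-call genotype error probability.
#' @param maf_dist MAF spectrum for the extra markers.
#' @param seed optional integer seed.
#' @return a [genotype_matrix()] sorted by (chrom, pos); DP/GQ are `NA`.
#' @export
simulate_array_panel <- function(truth, overlap_fraction = 1, n_extra = 0,
                                 error_rate = 0, maf_dist = c(0.05, 0.5),
                                 seed = NULL) {
  stopifnot(inherits(truth, "population_truth"),
            overlap_fraction >= 0, overlap_fraction <= 1,
            error_rate >= 0, error_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(truth$sites); ns <- length(truth$samples)
  n_shared <- round(overlap_fraction * nv)
  shared_idx <- sort(sample.int(nv, n_shared))
  sites <- truth$sites[shared_idx, , drop = FALSE]
  geno <- truth$geno[shared_idx, , drop = FALSE]
  if (n_extra > 0) {
    ord <- order(truth$sites$chrom, truth$sites$pos)
    gaps <- which(diff(truth$sites$pos[ord]) >= 2 &
                  truth$sites$chrom[ord][-nv] == truth$sites$chrom[ord][-1L])
    if (n_extra > length(gaps))
      stop("n_extra exceeds the number of inter-site gaps")
    host <- sort(sample(gaps, n_extra))
    hi <- ord[host]
    pos <- (truth$sites$pos[ord][host] + truth$sites$pos[ord][host + 1L]) %/% 2L
    q <- draw_maf(maf_dist, n_extra)
    al <- random_alleles(n_extra)
    extra_sites <- data.frame(chrom = truth$sites$chrom[hi], pos = pos,
                              ref = al$ref, alt = al$alt, maf = q,
                              stringsAsFactors = FALSE)
    if (!is.null(truth$blocks)) {
      b <- truth$blocks$block_of_site[hi]
      H <- truth$blocks$n_founders
      founder <- matrix(stats::rbinom(H * n_extra, 1L, rep(q, each = H)),
                        nrow = H)
      extra_geno <- matrix(0L, n_extra, ns)
      for (s in seq_len(ns)) {
        extra_geno[, s] <- founder[cbind(truth$blocks$hap1[s, b],
                                         seq_len(n_extra))] +
                           founder[cbind(truth$blocks$hap2[s, b],
                                         seq_len(n_extra))]
      }
    } else {
      extra_geno <- matrix(stats::rbinom(n_extra * ns, 2L,
                                         rep(q, ns)), nrow = n_extra)
    }
    sites <- rbind(sites, extra_sites)
    geno <- rbind(geno, extra_geno)
  }
  if (error_rate > 0) {
    flip <- which(stats::runif(length(geno)) < error_rate)
    shift <- sample(1:2, length(flip), replace = TRUE)
    geno[flip] <- (geno[flip] + shift) %% 3L
  }
  ord2 <- order(sites$chrom, sites$pos)
  genotype_matrix(truth$samples,
                  sites[ord2, c("chrom", "pos", "ref", "alt")],
                  matrix(dosage_to_gt(geno[ord2, , drop = FALSE]),
                         nrow = nrow(sites)))
}
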