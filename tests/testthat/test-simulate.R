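test_that("truth simulation follows Hardy-Weinberg proportions and is reproducible", {
  n <- 200; m <- 500
  tr <- simulate_truth(n, m, maf_dist = function(k) rep(0.5, k), seed = 1)
  het <- mean(tr$geno == 1L)
  se <- sqrt(0.5 * 0.5 / (n * m))
  expect_lt(abs(het - 0.5), 3 * se)
  # q -> 0 limit: essentially all hom-ref
  tr0 <- simulate_truth(50, 200, maf_dist = function(k) rep(1e-9, k), seed = 2)
  expect_true(all(tr0$geno == 0L))
  expect_error(simulate_truth(10, 10, maf_dist = c(0, 0.5), seed = 3))
  # determinism
  a <- simulate_truth(10, 20, seed = 7)
  b <- simulate_truth(10, 20, seed = 7)
  expect_identical(a, b)
  g1 <- simulate_gbs_calls(a, seed = 9)
  g2 <- simulate_gbs_calls(b, seed = 9)
  expect_identical(g1, g2)
})

test_that("calls equal truth in the infinite-depth error-free limit", {
  tr <- simulate_truth(10, 100, seed = 11)
  g <- simulate_gbs_calls(tr, depth_model("fixed", 1e6, zero_mass = 0),
                          artifact_model(dropout = 0, error_rate = 0),
                          seed = 12)
  expect_equal(g$gt, truth_as_matrix(tr)$gt, ignore_attr = TRUE)
  expect_true(all(g$gq == 99))
})

test_that("error-free homozygotes are never miscalled at any depth >= 1", {
  tr <- population_truth(sprintf("S%02d", 1:20),
                         data.frame(chrom = "1", pos = 1:400 * 10L,
                                    ref = "A", alt = "C", maf = 0.1),
                         matrix(rep(c(0L, 2L), each = 200), 400, 20))
  for (d in c(1, 2, 5)) {
    g <- simulate_gbs_calls(tr, depth_model("fixed", d, zero_mass = 0),
                            artifact_model(0, 0), seed = d)
    expect_equal(g$gt, truth_as_matrix(tr)$gt, ignore_attr = TRUE)
  }
})

test_that("het miscall rate at fixed depth matches the closed form", {
  tr <- all_het_truth(40, 500)   # 20,000 het calls per depth
  for (d in c(1, 2, 3, 5, 8)) {
    g <- simulate_gbs_calls(tr, depth_model("fixed", d, zero_mass = 0),
                            artifact_model(0, 0), seed = 100 + d)
    p <- het_miscall_prob(d)
    obs <- mean(g$gt != "0/1")
    se <- sqrt(p * (1 - p) / length(g$gt))
    expect_lt(abs(obs - p), 3 * se + 1e-12)
  }
})

test_that("full allele dropout converts every heterozygote to a homozygote", {
  tr <- all_het_truth(20, 200)
  g <- simulate_gbs_calls(tr, depth_model("fixed", 4, zero_mass = 0),
                          artifact_model(dropout = 1, error_rate = 0),
                          seed = 13)
  expect_true(all(g$gt %in% c("0/0", "1/1")))
})

test_that("default depth model yields the low-coverage call-rate regime", {
  tr <- simulate_truth(48, 3000, seed = 21)
  g <- simulate_gbs_calls(tr, seed = 22)
  expect_lt(abs(mean(sample_call_rate(g)) - 0.35), 0.05)
  # read-depth distribution: most calls carry fewer than 10 reads
  expect_gt(mean(g$dp < 10, na.rm = TRUE), 0.5)
  # per-variant call rates must spread, not concentrate at the mean
  expect_gt(stats::sd(variant_call_rate(g)), 0.05)
})

test_that("GQ is phred-calibrated for depth >= 2 and follows the closed form at depth 1", {
  tr <- simulate_truth(48, 4000, seed = 5)
  g <- simulate_gbs_calls(tr, seed = 6)
  truth_gt <- truth_as_matrix(tr)$gt
  ok <- !is.na(g$gt)
  err <- (g$gt != truth_gt)[ok]
  gq <- g$gq[ok]
  dp <- g$dp[ok]
  for (q in sort(unique(gq[gq >= 7]))) {
    sel <- gq == q
    if (sum(sel) < 300) next
    ub <- 10^(-(q - 0.5) / 10)   # bin upper bound after integer rounding
    expect_lte(mean(err[sel]), ub + 3 * sqrt(ub * (1 - ub) / sum(sel)))
  }
  # depth-1 calls: always called homozygous, wrong exactly when truth is
  # het; with q ~ U(0.05, 0.5) that is E[2q(1-q)] = 0.3649
  e1 <- mean(err[dp == 1])
  expect_lt(abs(e1 - 0.3649), 3 * sqrt(0.365 * 0.635 / sum(dp == 1)))
})

test_that("array panels copy truth, honour overlap counts and error rates", {
  tr <- simulate_truth(10, 2721, seed = 31)
  arr <- simulate_array_panel(tr, overlap_fraction = 1, seed = 32)
  expect_equal(arr$gt, truth_as_matrix(tr)$gt, ignore_attr = TRUE)
  # scale-down of a small shared-marker fraction: count is exact
  arr2 <- simulate_array_panel(tr, overlap_fraction = 16 / 2721, seed = 33)
  expect_equal(n_variants(arr2), 16L)
  expect_equal(nrow(suppressMessages(
    shared_markers(arr2, truth_as_matrix(tr)))), 16L)
  arr3 <- simulate_array_panel(tr, overlap_fraction = 0, n_extra = 50, seed = 34)
  g <- simulate_gbs_calls(tr, seed = 35)
  expect_equal(nrow(suppressMessages(shared_markers(arr3, g))), 0L)
  # genotype error flips change calls at roughly the requested rate
  arr4 <- simulate_array_panel(tr, overlap_fraction = 1, error_rate = 0.1, seed = 36)
  flipped <- mean(arr4$gt != truth_as_matrix(tr)$gt)
  expect_lt(abs(flipped - 0.1), 0.02)
})

test_that("block truth shows within-block linkage that extra array markers share", {
  tr <- simulate_block_truth(200, 200, block_length = 20, seed = 41)
  d <- tr$geno
  # founder-allele patterns give individual pairs correlations of either
  # sign, so linkage shows as |r|: averaged over many adjacent pairs it is
  # clearly higher within a block than across a block boundary
  pair_absr <- function(i, j) suppressWarnings(abs(cor(d[i, ], d[j, ])))
  within_idx <- setdiff(1:199, seq(20, 200, by = 20))   # boundaries at 20k/20k+1
  within <- mean(mapply(pair_absr, within_idx, within_idx + 1), na.rm = TRUE)
  across <- mean(mapply(pair_absr, seq(20, 180, by = 20),
                        seq(21, 181, by = 20)), na.rm = TRUE)
  expect_gt(within, across + 0.1)
  # extra array markers inherit the block structure: |r| with the nearest
  # truth marker is comparable to the within-block level
  arr <- simulate_array_panel(tr, overlap_fraction = 0, n_extra = 150, seed = 42)
  truth_m <- truth_as_matrix(tr)
  dos <- function(gt) c("0/0" = 0, "0/1" = 1, "1/1" = 2)[gt]
  rs <- sapply(seq_len(n_variants(arr)), function(j) {
    host <- which.min(abs(tr$sites$pos - arr$variants$pos[j]))
    suppressWarnings(abs(cor(dos(arr$gt[j, ]), dos(truth_m$gt[host, ]))))
  })
  expect_gt(mean(rs, na.rm = TRUE), across + 0.1)
})
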