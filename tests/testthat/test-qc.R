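test_that("call-level filtering applies RD and GQ thresholds to single calls", {
  m <- genotype_matrix("S1",
                       data.frame(chrom = "1", pos = c(10L, 20L, 30L),
                                  ref = "A", alt = "C"),
                       gt = matrix(c("0/1", "0/1", "0/1"), 3),
                       dp = matrix(c(3, 2, 5), 3),
                       gq = matrix(c(25, 99, 10), 3))
  f <- filter_calls(m, min_depth = 3, min_gq = 20)
  # (DP=3, GQ=25) retained; (DP=2, GQ=99) fails depth; (DP=5, GQ=10) fails GQ
  expect_equal(f$variants$pos, 10L)
  expect_equal(unname(f$gt[1, 1]), "0/1")
  # identity when thresholds are off
  expect_true(isTRUE(all.equal(filter_calls(m, 0, NULL), m)))
  # GQ threshold is inclusive: GQ == min_gq passes
  f20 <- filter_calls(genotype_matrix("S1",
                        data.frame(chrom = "1", pos = 1L, ref = "A", alt = "C"),
                        matrix("0/1"), matrix(5), matrix(20)),
                      min_depth = 0, min_gq = 20)
  expect_equal(n_variants(f20), 1L)
})

test_that("per-variant statistics count alleles and callable samples", {
  gt <- matrix(NA_character_, 3, 48)
  gt[1, 1:10] <- "0/0"                        # 10 of 48 known
  gt[2, 1:10] <- c(rep("0/0", 9), "0/1")      # MAF 1/20
  gt[3, ] <- "0/0"                            # monomorphic
  m <- genotype_matrix(sprintf("S%02d", 1:48),
                       data.frame(chrom = "1", pos = c(1L, 2L, 3L),
                                  ref = "A", alt = "C"),
                       gt)
  st <- per_variant_stats(m)
  expect_equal(st$call_rate[1], 10 / 48)
  expect_equal(st$maf[2], 0.05)
  expect_true(st$monomorphic[3])
  expect_equal(st$maf[3], 0)
})

test_that("variant-level filtering honours every threshold of the cascade", {
  v <- data.frame(chrom = c("1", "1", "X", "1"),
                  pos = c(10L, 20L, 30L, 40L),
                  ref = c("A", "C", "G", "T"),
                  alt = c("C", "A,G,T", "A", "C"))
  gt <- rbind(c(rep("0/1", 12), rep(NA, 36)),          # call rate 0.25
              c(rep("0/1", 48)),                        # 3 alt alleles
              c(rep("0/1", 48)),                        # chromosome X
              c(rep("0/0", 48)))                        # monomorphic
  m <- genotype_matrix(sprintf("S%02d", 1:48), v, gt)
  expect_equal(filter_variants(m, qc_config(max_alt = 1))$variants$pos,
               c(10L, 40L))
  expect_equal(filter_variants(m, qc_config(min_call_rate = 0.2,
                                            max_alt = 5,
                                            exclude_chroms = character(0)))$variants$pos,
               c(10L, 20L, 30L, 40L))
  expect_equal(filter_variants(m, qc_config(min_call_rate = 0.3, max_alt = 5,
                                            exclude_chroms = character(0)))$variants$pos,
               c(20L, 30L, 40L))
  expect_equal(filter_variants(m, qc_config(max_alt = 5,
                                            drop_monomorphic = TRUE,
                                            exclude_chroms = character(0)))$variants$pos,
               c(10L, 20L, 30L))
})

test_that("the dataset grid enumerates configurations and is monotone", {
  tr <- simulate_truth(30, 400, seed = 51)
  g <- simulate_gbs_calls(tr, seed = 52)
  grid <- dataset_grid(g, depth_levels = c(3, 4, 5, 6), gq_levels = list(NA, 20))
  expect_equal(nrow(grid$table), 8L)
  # counts non-increasing in min depth at fixed GQ setting
  for (gq_on in c(FALSE, TRUE)) {
    sel <- if (gq_on) !is.na(grid$table$min_gq) else is.na(grid$table$min_gq)
    tab <- grid$table[sel, ]
    tab <- tab[order(tab$min_depth), ]
    expect_true(all(diff(tab$n_variants) <= 0))
    expect_true(all(diff(tab$n_calls) <= 0))
  }
})

test_that("raising any threshold never increases retained variants or calls", {
  tr <- simulate_truth(30, 300, seed = 61)
  g <- simulate_gbs_calls(tr, seed = 62)
  count <- function(cfg) {
    f <- filter_variants(g, cfg)
    c(n_variants(f), sum(!is.na(f$gt)))
  }
  base <- qc_config(min_depth = 3, min_gq = 20, min_call_rate = 0.2,
                    min_maf = 0.02)
  for (harder in list(qc_config(4, 20, min_call_rate = 0.2, min_maf = 0.02),
                      qc_config(3, 30, min_call_rate = 0.2, min_maf = 0.02),
                      qc_config(3, 20, min_call_rate = 0.3, min_maf = 0.02),
                      qc_config(3, 20, min_call_rate = 0.2, min_maf = 0.05))) {
    expect_true(all(count(harder) <= count(base)))
  }
})

test_that("QC filtering is idempotent and matches the brute-force oracle", {
  tr <- simulate_truth(40, 500, seed = 71)
  g <- simulate_gbs_calls(tr, seed = 72)
  cfgs <- list(qc_config(3, 20, min_call_rate = 0.2, min_maf = 0.05),
               qc_config(4, NULL, min_call_rate = 0.3, min_maf = 0.02),
               qc_config(6, 20, min_call_rate = 0.4, min_maf = 0.05,
                         drop_monomorphic = TRUE))
  for (cfg in cfgs) {
    once <- filter_variants(g, cfg)
    twice <- filter_variants(once, cfg)
    expect_true(isTRUE(all.equal(once, twice)))
    keep <- brute_force_qc(g, cfg)
    oracle_variants <- g$variants[keep, c("chrom", "pos")]
    expect_equal(once$variants[, c("chrom", "pos")], oracle_variants,
                 ignore_attr = TRUE)
  }
})
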