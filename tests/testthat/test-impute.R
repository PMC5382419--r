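test_that("panel combination removes shared anchors and records evaluation loci", {
  v_gbs <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "C")
  v_arr <- data.frame(chrom = "1", pos = c(100L, 300L), ref = "A", alt = "C")
  gbs <- genotype_matrix(c("S1", "S2"), v_gbs,
                         rbind(c("0/1", NA), c("0/0", "1/1")),
                         dp = matrix(5, 2, 2), gq = matrix(50, 2, 2))
  arr <- genotype_matrix(c("S1", "S2"), v_arr,
                         rbind(c("0/1", "0/1"), c("0/0", "0/0")))
  cp <- combine_panels(gbs, arr)
  expect_equal(cp$matrix$variants$pos, c(100L, 200L, 300L))
  expect_equal(cp$origin, c("GBS", "GBS", "anchor"))
  expect_equal(cp$evaluation_loci$pos, 100L)
  # anchor subset of GBS: merged panel is GBS only
  cp2 <- combine_panels(gbs, subset_matrix(arr, variants = 1))
  expect_equal(cp2$matrix$variants$pos, c(100L, 200L))
  expect_equal(sum(cp2$origin == "anchor"), 0L)
  # disjoint panels: union, no evaluation loci
  cp3 <- combine_panels(gbs, subset_matrix(arr, variants = 2))
  expect_equal(cp3$matrix$variants$pos, c(100L, 200L, 300L))
  expect_equal(nrow(cp3$evaluation_loci), 0L)
  expect_error(combine_panels(gbs, genotype_matrix("OTHER", v_arr,
                                                   matrix(c("0/0", "0/0")))),
               "sample")
})

test_that("k-NN imputation recovers a duplicated sample and falls back to majority", {
  set.seed(7)
  tr <- simulate_truth(10, 120, maf_dist = c(0.2, 0.5), seed = 7)
  full <- truth_as_matrix(tr)
  # duplicate sample S001 as TWIN, then mask half of TWIN's calls
  twin <- genotype_matrix(c(full$samples, "TWIN"),
                          full$variants,
                          cbind(full$gt, full$gt[, 1]))
  masked <- twin
  hide <- sample(n_variants(twin), 60)
  masked$gt[hide, "TWIN"] <- NA
  res <- impute_knn(masked, window = 21, k = 1)
  expect_equal(res$matrix$gt[hide, "TWIN"], twin$gt[hide, "TWIN"])
  expect_true(all(res$imputed[hide, ncol(twin$gt)]))

  # majority fallback: a locus where no neighbour has window overlap
  v <- data.frame(chrom = "1", pos = (1:3) * 10L, ref = "A", alt = "C")
  gt <- rbind(rep("0/0", 48),
              c(NA, rep("0/0", 46), "0/1"),
              rep("0/0", 48))
  gt[1, 1] <- NA; gt[3, 1] <- NA   # target sample has no informative markers
  m <- genotype_matrix(sprintf("S%02d", 1:48), v, gt)
  res2 <- impute_knn(m, window = 3, k = 5, min_overlap = 1)
  expect_equal(unname(res2$matrix$gt[2, 1]), "0/0")   # locus major genotype
})

test_that("imputation is deterministic, complete and never alters observed calls", {
  tr <- simulate_block_truth(30, 300, seed = 17)
  g <- simulate_gbs_calls(tr, seed = 18)
  g <- filter_variants(g, qc_config(min_depth = 2))
  res <- impute_knn(g)
  obs <- !is.na(g$gt)
  expect_identical(res$matrix$gt[obs], g$gt[obs])
  expect_false(any(is.na(res$matrix$gt)))
  expect_identical(res$imputed, !obs)
  res2 <- impute_knn(g)
  expect_identical(res$matrix$gt, res2$matrix$gt)
  # a panel with no missing calls is returned unchanged
  full <- truth_as_matrix(tr)
  res3 <- impute_knn(full)
  expect_identical(res3$matrix$gt, full$gt)
  expect_false(any(res3$imputed))
})

test_that("imputation scoring uses imputed calls at evaluation loci only", {
  tr <- simulate_truth(20, 150, seed = 27)
  full <- truth_as_matrix(tr)
  masked <- full
  set.seed(28)
  hide <- matrix(runif(length(masked$gt)) < 0.3, nrow(masked$gt))
  masked$gt[hide] <- NA
  # an imputer that copies truth scores 100%
  copy_truth <- function(panel, ...) {
    out <- panel; out$gt <- full$gt
    structure(list(matrix = out, imputed = is.na(panel$gt)),
              class = "imputation_result")
  }
  ct <- evaluate_imputation(copy_truth(masked), full)
  expect_equal(ct$accuracy, 100.0)
  expect_equal(ct$n_compared, sum(hide))
  # restricting the evaluation loci restricts the scored calls
  loci <- full$variants[1:10, c("chrom", "pos")]
  ct2 <- evaluate_imputation(copy_truth(masked), full, loci)
  expect_equal(ct2$n_compared, sum(hide[1:10, ]))
  # zero imputed calls at evaluation loci -> undefined accuracy
  ct3 <- evaluate_imputation(copy_truth(full), full)
  expect_true(is.na(ct3$accuracy))
})

test_that("random guessing on q=0.5 HWE loci scores the closed-form 37.5%", {
  tr <- simulate_truth(60, 400, maf_dist = function(k) rep(0.5, k), seed = 37)
  full <- truth_as_matrix(tr)
  masked <- full
  set.seed(38)
  hide <- matrix(runif(length(masked$gt)) < 0.5, nrow(masked$gt))
  masked$gt[hide] <- NA
  random_imputer <- function(panel, ...) {
    out <- panel
    miss <- is.na(panel$gt)
    # guesses drawn from the same HWE(0.5) class distribution
    out$gt[miss] <- sample(c("0/0", "0/1", "1/1"), sum(miss), replace = TRUE,
                           prob = c(0.25, 0.5, 0.25))
    structure(list(matrix = out, imputed = miss),
              class = "imputation_result")
  }
  set.seed(39)
  ct <- evaluate_imputation(random_imputer(masked), full)
  # sum over classes of p_true * p_guess = 1/16 + 1/4 + 1/16 = 0.375
  se <- 100 * sqrt(0.375 * 0.625 / ct$n_compared)
  expect_lt(abs(ct$accuracy - 37.5), 3 * se)
})

test_that("an external imputer plugs in through the VCF round-trip contract", {
  tr <- simulate_truth(8, 30, seed = 57)
  g <- simulate_gbs_calls(tr, seed = 58)
  # a minimal external "imputer": fill every missing call with hom-ref
  cmd <- "sed -e 's@\\./\\.:\\.:\\.@0/0:.:.@g' {in} > {out}"
  res <- impute_external(g, cmd)
  was_obs <- !is.na(g$gt)
  expect_identical(res$matrix$gt[was_obs], g$gt[was_obs])
  expect_true(all(res$matrix$gt[!was_obs] == "0/0"))
  expect_identical(unname(res$imputed), unname(!was_obs))
  # a command that breaks the contract (drops variants) is rejected
  expect_error(impute_external(g, "head -n 8 {in} > {out}"), "variants")
})

test_that("the imputation grid row for one config equals a single evaluation", {
  tr <- simulate_block_truth(24, 200, seed = 47)
  g <- simulate_gbs_calls(tr, seed = 48)
  truth_m <- truth_as_matrix(tr)
  grid <- dataset_grid(g, depth_levels = 2, gq_levels = list(NA),
                       call_rate_levels = 0.2)
  res <- imputation_grid(grid, anchor = NULL, truth = truth_m)
  expect_equal(nrow(res), 1L)
  ds <- grid$datasets[[1]]
  pairs <- suppressMessages(shared_markers(ds, truth_m))
  loci <- ds$variants[pairs$idx_a, c("chrom", "pos")]
  direct <- evaluate_imputation(impute_knn(ds), truth_m, loci)
  expect_equal(res$accuracy, direct$accuracy)
  expect_equal(res$n_imputed_scored, direct$n_compared)
})
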