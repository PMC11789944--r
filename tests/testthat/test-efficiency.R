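test_that("expected counts are ancestor counts scaled by relative CN", {
  anc <- matrix(c(100L, 50L, 30L, 70L), 2, 2,
                dimnames = list(c("g1", "g2"), c("a:1", "a:2")))
  expect_equal(unname(expectedCounts(anc, c(3, 1))[1, ]), c(300, 90))
  expect_equal(unname(expectedCounts(anc, c(1, 1))), unname(anc) * 1.0)
  # ancestor CN 2, evolved CN 4 -> relative CN 2
  cn <- matrix(c(2L, 4L), 1, 2, dimnames = list("g1", c("anc", "evo")))
  expect_equal(unname(relativeCopyNumber(cn, "evo", "anc")), 2)
  expect_equal(unname(expectedCounts(anc[1, , drop = FALSE], 2)[1, ]),
               c(200, 60))
})

test_that("relative copy number is validated against a depth-ratio oracle", {
  p <- simulationParams(n_genes = 200, n_cnv_genes = 60, core_size = 17,
                        cnv_cn_values = 4L, rna_depth = 5e3,
                        fraction_affected = c(txn = 0, tln = 0, prot = 0),
                        rng_seed = 17)
  truth <- simulateTruth(p)
  m <- SummarizedExperiment::assay(simulateCounts(p, truth)$rna)
  st <- vapply(strsplit(colnames(m), ":"), `[`, "", 1)
  depth_ratio <- rowMeans(m[, st == "evolved2"]) /
    rowMeans(m[, st == "ancestor"])
  rcn <- truth$cn_evolved2 / truth$cn_ancestor
  expect_equal(median(depth_ratio[rcn == 4]), 4, tolerance = 0.1)
})

test_that("NB test is centered when observed equals expected", {
  obs <- matrix(c(500L, 520L, 200L, 190L), 2, 2,
                dimnames = list(c("g1", "g2"), NULL))
  res <- txnEfficiencyTest(obs, obs)
  expect_true(all(res$p > 0.999))
  expect_true(all(res$call == "none"))
  expect_true(all(res$bh_adj_p >= res$p))
})

test_that("NB test flags strong attenuation and respects BH ordering", {
  set.seed(2)
  n <- 300
  anc <- matrix(rnbinom(n * 2, mu = 1000, size = 20), n,
                dimnames = list(paste0("g", 1:n), NULL))
  obs <- matrix(rnbinom(n * 2, mu = 1000, size = 20), n,
                dimnames = list(paste0("g", 1:n), NULL))
  res <- txnEfficiencyTest(obs, expectedCounts(anc, rep(3, n)))
  expect_gt(mean(res$call == "lower"), 0.9)
  expect_true(all(res$log2_ratio_obs_vs_exp < 0))
})

test_that("translation FET matches its definition and handles zeros", {
  mk <- function(rpf_evo, rna_evo, rpf_anc, rna_anc) {
    cols <- c("evolved1:1", "evolved1:2", "ancestor:1", "ancestor:2")
    smp <- data.frame(strain = c("evolved1", "evolved1",
                                 "ancestor", "ancestor"))
    rpf <- matrix(rep(c(rpf_evo, rpf_anc), each = 2), 1, 4,
                  dimnames = list("g1", cols), byrow = TRUE)
    rna <- matrix(rep(c(rna_evo, rna_anc), each = 2), 1, 4,
                  dimnames = list("g1", cols), byrow = TRUE)
    tlnEfficiencyFet(rpf, rna, smp, smp, "evolved1", "ancestor")
  }
  flat <- mk(100, 100, 100, 100)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p, 1)
  expect_equal(flat$call, "none")

  up <- mk(200, 100, 100, 100)
  expect_equal(up$odds_ratio, 2)
  expect_equal(up$p, fetOracle(200, 100, 100, 100), tolerance = 1e-12)

  zero <- mk(100, 0, 100, 100)
  expect_true(zero$excluded)
  expect_equal(zero$reason, "zero_cell_after_rounding")
})

test_that("swapping the FET rows inverts the odds ratio, p unchanged", {
  tab <- matrix(c(180, 90, 120, 140), 2, 2, byrow = TRUE)
  p1 <- fisher.test(tab)$p.value
  p2 <- fisher.test(tab[2:1, ])$p.value
  or1 <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  or2 <- (tab[2, 1] * tab[1, 2]) / (tab[2, 2] * tab[1, 1])
  expect_equal(p1, p2)
  expect_equal(or2, 1 / or1)
})
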