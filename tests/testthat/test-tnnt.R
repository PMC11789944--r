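test_that("GLM outlier test flags planted outliers and only those", {
  set.seed(6)
  n <- 1000
  ep <- rlnorm(n, 6, 1)
  al <- rlnorm(n, 6, 1)
  ap <- rlnorm(n, 6, 1)
  y_lin <- 2 * ep + 0.5 * al - 0.2 * ap + 3
  # exactly linear response: residuals are all ~0, nothing flagged
  expect_true(all(!glmOutlier(y_lin, ep, al, ap)$flagged))

  y <- y_lin + rnorm(n, 0, 1)
  y[17] <- y[17] + 10 * sd(y - y_lin) # one gene displaced by ~10 sd
  res <- glmOutlier(y, ep, al, ap)
  expect_true(res$flagged[17])
  expect_equal(res$direction[17], "higher")

  # strict inequality at the threshold: no residual exceeds its own max
  thr <- max(abs(res$standardized_residual))
  expect_true(all(!glmOutlier(y, ep, al, ap, threshold = thr)$flagged))
})

test_that("GLM flags are invariant to affine rescaling of a predictor", {
  set.seed(7)
  n <- 400
  ep <- rlnorm(n, 6, 1); al <- rlnorm(n, 6, 1); ap <- rlnorm(n, 6, 1)
  y <- 2 * ep + 0.5 * al + rnorm(n, 0, 5)
  f1 <- glmOutlier(y, ep, al, ap)
  f2 <- glmOutlier(y, 1000 * ep + 7, al, ap)
  expect_equal(f1$standardized_residual, f2$standardized_residual,
               tolerance = 1e-8)
})

test_that("TNNT handles degenerate and extreme inputs per contract", {
  expect_error(tnnt(runif(10), runif(10)), ">= 20")

  set.seed(1)
  cfg <- pipelineConfig(rng_seed = 1)
  n <- 200
  a <- runif(n, 0.4, 0.6)
  e <- a * exp(rnorm(n, 0, 0.01))
  e[1] <- a[1] * 10 # score 10x any neighbor
  res <- tnnt(setNames(e, paste0("g", 1:n)), a, NULL, cfg)
  expect_equal(res$fdr[1], 0)
  expect_equal(res$call[1], "higher")
  expect_equal(res$distance_rank[1], 1L)
  # neighborhood size respected: all fdr estimable, in [0, 1]
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))

  # identical efficiencies: no gene can be an outlier
  same <- tnnt(setNames(a, paste0("g", 1:n)), a, NULL, cfg)
  expect_true(all(same$call == "none"))
})

test_that("the replicate-range filter disqualifies noisy genes", {
  set.seed(2)
  cfg <- pipelineConfig(rng_seed = 2)
  n <- 100
  a <- runif(n, 0.4, 0.6)
  e <- a + 0.002
  e[5] <- a[5] + 0.4 # huge distance, should be called...
  rng <- rep(0, n)
  rng[5] <- 0.9 # ...but its replicates disagree more than the strains do
  res <- tnnt(setNames(e, paste0("g", 1:n)), a, rng, cfg)
  expect_true(res$variance_filtered[5])
  expect_equal(res$call[5], "none")
  res2 <- tnnt(setNames(e, paste0("g", 1:n)), a, NULL, cfg)
  expect_equal(res2$call[5], "higher")
})

test_that("TNNT fdr is invariant under joint positive rescaling", {
  set.seed(3)
  cfg <- pipelineConfig(rng_seed = 3)
  n <- 150
  a <- runif(n, 0.2, 1)
  e <- a * exp(rnorm(n, 0, 0.1))
  r1 <- tnnt(e, a, NULL, cfg)
  r2 <- tnnt(5 * e, 5 * a, NULL, cfg)
  expect_equal(r1$fdr, r2$fdr)
  expect_equal(r1$distance_rank, r2$distance_rank)
})

test_that("TNNTg combines calls additively with TNNT precedence", {
  tn <- data.frame(gene_id = c("a", "b", "c", "d"),
                   call = c("higher", "none", "none", "lower"))
  gl <- data.frame(gene_id = c("a", "b", "c", "d"),
                   direction = c("none", "lower", "none", "higher"))
  comb <- tnntg(tn, gl)
  expect_equal(comb$call, c("higher", "lower", "none", "lower"))
  expect_equal(comb$direction_conflict, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("benchmark metrics match hand-computed values", {
  perfect <- benchmarkCalls(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$fnr, 0)

  none <- benchmarkCalls(rep(FALSE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(none$f1, 0)
  expect_equal(none$fnr, 1)

  # tp=2 fp=1 fn=2: precision 2/3, recall 1/2, F1 = 2PR/(P+R) = 4/7
  m <- benchmarkCalls(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                      c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1 / 2)
  expect_equal(m$f1, 0.5714, tolerance = 1e-4)

  empty <- benchmarkCalls(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(empty$f1))
})

test_that("efficiencyOutliers returns a coherent per-gene table", {
  sim <- smallSim()
  cfg <- pipelineConfig(rng_seed = 5)
  qc <- qcFilter(sim$moe, cfg)
  sub <- subsetGenes(sim$moe, qc$retained)
  res <- efficiencyOutliers(sub, "evolved1", "MS/RPF", cfg)
  expect_equal(nrow(res), length(qc$retained))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_true(all(res$call[res$tnnt_call != "none"] != "none"))
  # TNNTg is at least as inclusive as either component
  expect_true(all(res$call != "none" |
                  (res$tnnt_call == "none" & res$glm_direction == "none")))
})
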