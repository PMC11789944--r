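test_that("QC thresholds are inclusive and remove the right genes", {
  mk <- function(rna_g1) {
    strains <- c("ancestor", "evolved1")
    cols <- c("ancestor:1", "ancestor:2", "evolved1:1", "evolved1:2")
    rna <- matrix(200L, 4, 4, dimnames = list(paste0("g", 1:4), cols))
    rna["g1", c("evolved1:1", "evolved1:2")] <- as.integer(rna_g1 / 2)
    rpf <- matrix(5L, 4, 4, dimnames = dimnames(rna)) # 10 per strain: boundary
    ms <- matrix(1e5, 4, 8, dimnames = list(
      rownames(rna), paste0(rep(strains, each = 4), ":", 1:4)))
    ms["g2", ] <- NA # not detected anywhere
    cn <- matrix(1L, 4, 2, dimnames = list(rownames(rna), strains))
    gd <- S4Vectors::DataFrame(
      gene_id = rownames(rna), chrom = "chrI", start = 0L, end = 10L,
      strand = "+", cds_length = 10L, tl_start = NA_integer_,
      tl_end = NA_integer_,
      transposon_associated = c(FALSE, FALSE, TRUE, FALSE))
    MultiOmicsExperiment(makeLevelSE(rna), makeLevelSE(rpf), makeLevelSE(ms),
                         gd, cn, ancestor = "ancestor")
  }
  # 99 RNA reads in one strain -> removed; exactly 100 -> retained
  qc99 <- qcFilter(mk(99))
  expect_false("g1" %in% qc99$retained)
  qc100 <- qcFilter(mk(100))
  expect_true("g1" %in% qc100$retained)
  # MS-undetected and transposon-associated genes removed despite counts
  expect_false(any(c("g2", "g3") %in% qc100$retained))
  expect_true("g4" %in% qc100$retained)
})

test_that("QC is monotone in its thresholds", {
  sim <- smallSim()
  base <- qcFilter(sim$moe, pipelineConfig())
  relaxed <- qcFilter(sim$moe, pipelineConfig(min_rna_reads = 50,
                                              min_rpf_reads = 5))
  expect_true(all(base$retained %in% relaxed$retained))
})

test_that("TPM columns sum to one million with equal-rate examples", {
  m1 <- matrix(7L, 1, 2, dimnames = list("g1", c("a:1", "a:2")))
  expect_equal(unname(tpm(m1, 500)[1, ]), c(1e6, 1e6))

  m2 <- matrix(c(50, 100), 2, 1, dimnames = list(c("g1", "g2"), "a:1"))
  expect_equal(unname(tpm(m2, c(500, 1000))[, 1]), c(5e5, 5e5))

  m3 <- matrix(c(10, 20, 30), 3, 1)
  expect_equal(unname(tpm(m3, c(100, 200, 300))[, 1]),
               rep(1e6 / 3, 3), tolerance = 1e-9)

  sim <- smallSim()
  tp <- tpm(rnaCounts(sim$moe), geneData(sim$moe)$cds_length)
  expect_equal(unname(colSums(tp)), rep(1e6, ncol(tp)), tolerance = 1e-6)
  expect_error(tpm(matrix(0, 2, 1), c(10, 10)), "all-zero")
})

test_that("replicate summaries give medians and ranges", {
  m <- matrix(c(10, 20, 5, 5, 1, 100), nrow = 1)
  colnames(m) <- paste0(c("a", "a", "b", "b", "c", "c"), ":", 1:6)
  smp <- data.frame(strain = c("a", "a", "b", "b", "c", "c"))
  expect_equal(summarizeReplicates(m, smp, "a")$median, 15)
  expect_equal(summarizeReplicates(m, smp, "a")$range, 10)
  expect_equal(summarizeReplicates(m, smp, "b")$range, 0)
  m5 <- matrix(c(1, 2, 3, 4, 100), nrow = 1)
  colnames(m5) <- paste0("a:", 1:5)
  expect_equal(
    summarizeReplicates(m5, data.frame(strain = rep("a", 5)), "a")$median, 3)
})

test_that("Box-Cox + MinMax maps to (epsilon, 1], keeps order, inverts", {
  set.seed(4)
  x <- rlnorm(500, 5, 1.2)
  tr <- boxCoxMinMax(x)
  expect_equal(max(tr$values), 1)
  expect_true(all(tr$values > 0))
  expect_identical(order(tr$values), order(x))
  back <- invertTransform(tr$values, tr$record)
  expect_equal(back, x, tolerance = 1e-8)
  # zeros are handled by the +1 offset, still strictly positive output
  tr0 <- boxCoxMinMax(c(0, x))
  expect_equal(tr0$record@offset, 1)
  expect_true(all(tr0$values > 0))
  expect_error(boxCoxMinMax(rep(3, 10)), "degenerate")
})

test_that("the transform gaussianizes log-normal data", {
  set.seed(11)
  x <- rlnorm(1e4, 8, 1)
  tr <- boxCoxMinMax(x)
  y <- tr$values
  skew <- mean((y - mean(y))^3) / sd(y)^3
  expect_lt(abs(skew), 0.1)
})
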