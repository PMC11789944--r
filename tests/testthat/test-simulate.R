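test_that("generators are pure functions of (params, seed)", {
  p <- smallParams(n_genes = 150, seed = 99)
  s1 <- simulateExperiment(p)
  s2 <- simulateExperiment(p)
  expect_identical(rnaCounts(s1$moe), rnaCounts(s2$moe))
  expect_identical(msIntensities(s1$moe), msIntensities(s2$moe))
  expect_identical(as.character(s1$tls), as.character(s2$tls))
  expect_identical(s1$coverage, s2$coverage)
})

test_that("RNA means scale with copy number when attenuation is 1", {
  # sample-mean oracle at high depth: CN 3, no attenuation -> 3x ancestor
  p <- simulationParams(n_genes = 200, n_cnv_genes = 40, core_size = 17,
                        cnv_cn_values = 3L, rna_depth = 1e4,
                        n_rna_reps = 20L,
                        fraction_affected = c(txn = 0, tln = 0, prot = 0),
                        transposon_fraction = 0, ms_missing_fraction = 0,
                        rng_seed = 21)
  truth <- simulateTruth(p)
  counts <- simulateCounts(p, truth)
  m <- SummarizedExperiment::assay(counts$rna)
  st <- vapply(strsplit(colnames(m), ":"), `[`, "", 1)
  cnv <- truth$cn_evolved1 == 3
  # geometric mean of per-gene mean ratios: replicate-averaging cancels
  # the log bias, leaving the planted CN factor
  gratio <- function(keep) {
    r <- rowMeans(m[keep, st == "evolved1"]) /
      rowMeans(m[keep, st == "ancestor"])
    exp(mean(log(r)))
  }
  expect_equal(gratio(cnv), 3, tolerance = 0.03)
  expect_equal(gratio(!cnv), 1, tolerance = 0.03)
})

test_that("zero dispersion gives Poisson-like counts", {
  p <- simulationParams(n_genes = 500, nb_dispersion = 0, rna_depth = 1000,
                        fraction_affected = c(txn = 0, tln = 0, prot = 0),
                        rng_seed = 3)
  truth <- simulateTruth(p)
  m <- SummarizedExperiment::assay(simulateCounts(p, truth)$rna)
  st <- vapply(strsplit(colnames(m), ":"), `[`, "", 1)
  anc <- m[truth$cn_evolved1 == 1, st == "ancestor"]
  # index of dispersion across genes of equal mean ~ 1 under Poisson
  idx <- apply(anc, 1, var) / rowMeans(anc)
  expect_equal(mean(idx), 1, tolerance = 0.15)
})

test_that("MS intensities track protein effects and the RPF scale", {
  p <- simulationParams(n_genes = 200, ms_lognormal_sigma = 0,
                        ms_missing_fraction = 0,
                        fraction_affected = c(txn = 0, tln = 0, prot = 0.2),
                        prot_effect = 2, rng_seed = 8)
  truth <- simulateTruth(p)
  ms <- SummarizedExperiment::assay(simulateMs(p, truth))
  st <- vapply(strsplit(colnames(ms), ":"), `[`, "", 1)
  # sigma = 0 -> deterministic: replicates identical
  evo <- ms[, st == "evolved1"]
  expect_true(all(evo == evo[, 1]))
  # planted 0.5x protein effect halves the evolved/ancestor MS ratio
  # relative to unaffected genes (RPF means cancel in the double ratio)
  ratio <- evo[, 1] / ms[, st == "ancestor"][, 1]
  down <- truth$prot_effect == 0.5 & truth$cn_evolved1 == 1
  null <- truth$prot_effect == 1 & truth$cn_evolved1 == 1
  expect_equal(median(ratio[down]) / median(ratio[null]), 0.5,
               tolerance = 1e-8)
  # intensity scale sits orders of magnitude above the count scale
  expect_gt(median(ms, na.rm = TRUE) / p$rpf_depth, 100)
})

test_that("planted TL features lie in bounds and leave coverage signatures", {
  sim <- smallSim()
  truth <- sim$truth
  for (i in which(truth$has_uorf)) {
    expect_lte(truth$uorf_start[i] + truth$uorf_length[i], truth$tl_length[i])
    expect_equal(truth$uorf_length[i] %% 3, 0)
    cov <- sim$coverage[[truth$gene_id[i]]]
    st <- truth$uorf_start[i]
    len <- truth$uorf_length[i]
    inside <- (st + 1):(st + len)
    frame0 <- inside[seq(1, len, by = 3)]
    other <- setdiff(seq_len(nrow(cov)), inside)
    # elevated, 3-periodic coverage over the planted uORF
    expect_gt(mean(cov[frame0, ]), 5 * max(mean(cov[other, ]), 0.05))
    expect_gt(mean(cov[frame0, ]), 2 * mean(cov[setdiff(inside, frame0), ]))
  }
  for (i in which(truth$has_motif)) {
    pos <- as.integer(strsplit(truth$motif_positions[i], ",")[[1]])
    expect_true(all(pos + 8 <= truth$tl_length[i]))
    s <- as.character(sim$tls[[truth$gene_id[i]]])
    for (pp in pos) {
      expect_match(substr(s, pp + 1, pp + 8), "^C[ACGT][CT]TC[ACGT][CT]T$")
    }
  }
})

test_that("motif-free TLs contain only chance matches at the 1/1024 rate", {
  p <- simulationParams(n_genes = 400, motif_fraction = 0, uorf_fraction = 0,
                        tl_length_meanlog = log(300), rng_seed = 31)
  truth <- simulateTruth(p)
  tl <- simulateTls(p, truth)
  hits <- sum(vapply(as.character(tl$tls), function(s) {
    nrow(scanMotif(s))
  }, 0))
  # uniform base composition: per position per strand P(match) = 1/1024
  n_pos <- sum(nchar(as.character(tl$tls)) - 7) * 2
  expected <- n_pos / 1024
  expect_lt(abs(hits - expected), 3 * sqrt(expected) + 1)
})
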