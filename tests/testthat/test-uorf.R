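test_that("candidate enumeration respects ORF structure and length bounds", {
  one <- enumerateCandidates("ATGAAATAA")
  expect_equal(nrow(one), 1)
  expect_equal(one$tl_offset, 0)
  expect_equal(one$length, 9)
  expect_equal(one$start_codon, "ATG")

  minimal <- enumerateCandidates("ATGTAA")
  expect_equal(minimal$length, 6)

  # RNA alphabet accepted
  expect_equal(nrow(enumerateCandidates("AUGAAAUAA")), 1)

  expect_equal(nrow(enumerateCandidates("AUGUA")), 0) # shorter than 6 nt

  # ORF longer than 300 nt is excluded
  long_tl <- paste0("ATG", strrep("AAA", 100), "TAA") # 306 nt + stop
  expect_false(any(enumerateCandidates(long_tl)$tl_offset == 0))

  # overlapping and nested candidates are all reported
  nested <- enumerateCandidates("ATGATGAAATAA")
  expect_equal(sort(nested$tl_offset), c(0, 3))

  # no in-frame stop inside the TL -> no candidate
  expect_equal(nrow(enumerateCandidates("ATGAAAAAAAAA")), 0)
})

test_that("coverage features capture periodicity and initiation contrast", {
  cand <- list(tl_offset = 12L, length = 30L, is_aug = TRUE)
  uniform <- rep(2, 60)
  f <- extractFeatures(cand, uniform)
  expect_equal(unname(f["inframe"]), 1 / 3, tolerance = 1e-9)

  frame0 <- rep(0, 60)
  frame0[seq(13, 42, by = 3)] <- 6
  f0 <- extractFeatures(cand, frame0)
  expect_equal(unname(f0["inframe"]), 1)
  expect_gt(unname(f0["upstream_contrast"]), 10)

  zero <- extractFeatures(cand, rep(0, 60))
  expect_true(all(is.finite(zero)))
})

test_that("triplet shuffling preserves the triplet multiset", {
  tripletsOf <- function(s) {
    n <- nchar(s) %/% 3 * 3
    sort(substring(s, seq(1, n, 3), seq(3, n, 3)))
  }
  s <- "ATGCCCGTAAGGTTTAC" # 17 nt: 5 triplets + 2 nt remainder
  cov <- matrix(seq_len(17 * 2), ncol = 2)
  null <- tripletShuffleNull(s, cov, n_shuffles = 10, seed = 1)
  expect_true(is.data.frame(null))
  # direct check of the shuffle primitive
  set.seed(1)
  sh <- CNVeff:::shuffleTriplets(s, cov, sample.int(5))
  expect_identical(tripletsOf(sh$seq), tripletsOf(s))
  expect_identical(substr(sh$seq, 16, 17), substr(s, 16, 17))
  expect_identical(sort(sh$coverage[, 1]), sort(cov[, 1]))

  # homopolymer: every shuffle is the identity
  hp <- strrep("A", 12)
  sh2 <- CNVeff:::shuffleTriplets(hp, matrix(0, 12, 1), sample.int(4))
  expect_identical(sh2$seq, hp)
})

test_that("high-confidence calls are the intersection of replicate calls", {
  p <- smallParams(n_genes = 300, seed = 13)
  truth <- simulateTruth(p)
  tl <- simulateTls(p, truth)
  cfg <- pipelineConfig(rng_seed = 13, classifier = "logistic")
  res <- suppressWarnings(
    callUorfs(tl$tls, tl$coverage, validatedFromTruth(truth), cfg))
  cc <- res$candidates
  expect_true(all(cc$high_confidence == (cc$called_rep1 & cc$called_rep2)))
  expect_lte(sum(cc$high_confidence), sum(cc$called_rep1))
  expect_lte(sum(cc$high_confidence), sum(cc$called_rep2))
  expect_true(all(cc$score_rep1 >= 0 & cc$score_rep1 <= 1))
  # calls are reproducible under a fixed seed
  res2 <- suppressWarnings(
    callUorfs(tl$tls, tl$coverage, validatedFromTruth(truth), cfg))
  expect_identical(res$candidates$high_confidence,
                   res2$candidates$high_confidence)
})

test_that("planted uORFs score above background and are recovered", {
  p <- smallParams(n_genes = 300, seed = 13)
  truth <- simulateTruth(p)
  tl <- simulateTls(p, truth)
  cfg <- pipelineConfig(rng_seed = 13)
  res <- suppressWarnings(
    callUorfs(tl$tls, tl$coverage, validatedFromTruth(truth), cfg))
  cc <- res$candidates
  v <- validatedFromTruth(truth)
  key <- paste(cc$gene_id, cc$tl_offset)
  vkey <- paste(v$gene_id, v$tl_offset)
  planted <- key %in% vkey
  # planted candidates carry a strong start-peak signature
  expect_gt(median(cc$raw_score[planted]), 2)
  called <- cc$high_confidence
  recall <- sum(called & planted) / nrow(v)
  precision <- sum(called & planted) / sum(called)
  expect_gt(recall, 0.7)
  expect_gt(precision, 0.7)
})

test_that("noise-only coverage yields few high-confidence calls", {
  p <- smallParams(n_genes = 200, seed = 23, uorf_fraction = 0)
  truth <- simulateTruth(p)
  tl <- simulateTls(p, truth)
  # no planted uORFs: train on a synthetic positive set from another run
  # is impossible, so check the null threshold screens candidates instead
  cand_scores <- unlist(lapply(truth$gene_id, function(g) {
    cc <- enumerateCandidates(as.character(tl$tls[[g]]))
    if (!nrow(cc)) return(numeric())
    vapply(seq_len(nrow(cc)), function(i) {
      CNVeff:::rawUorfScore(cc[i, ], tl$coverage[[g]])
    }, 0)
  }))
  nulls <- do.call(rbind, lapply(seq_along(truth$gene_id), function(i) {
    g <- truth$gene_id[i]
    tripletShuffleNull(as.character(tl$tls[[g]]), tl$coverage[[g]],
                       n_shuffles = 3, seed = i)
  }))
  thr <- quantile(nulls$score, 0.95)
  expect_lt(mean(cand_scores > thr), 0.07)
})
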