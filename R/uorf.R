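#' @importFrom stats glm binomial predict quantile
NULL

# canonical start plus all single-mismatch near-cognates (DNA alphabet)
#' Start codons considered by the uORF caller
#' @param near_cognate include near-cognate starts.
#' @return character vector of DNA codons.
#' @export
uorfStartCodons <- function(near_cognate = TRUE) {
  aug <- "ATG"
  if (!near_cognate) return(aug)
  c(aug, "CTG", "GTG", "TTG", "ACG", "ATA", "ATT", "ATC", "AAG", "AGG")
}

normalizeSeq <- function(s) {
  toupper(chartr("Uu", "Tt", as.character(s)))
}

#' Enumerate candidate uORFs in a transcript leader
#'
#' Reports every ORF that begins at an allowed start codon and runs to
#' the first in-frame stop codon entirely inside the TL, with length
#' (start through stop, inclusive) within the configured range.
#' Overlapping and nested candidates are all reported.
#'
#' @param tl_seq TL sequence (character or DNAString; RNA or DNA
#'   alphabet).
#' @param start_codons allowed start codons (DNA alphabet).
#' @param length_range inclusive length bounds in nucleotides.
#' @return data.frame: tl_offset (0-based), length, start_codon, frame
#'   (start offset relative to the TL 3' end, i.e. the mORF reading
#'   frame), is_aug.
#' @export
enumerateCandidates <- function(tl_seq,
                                start_codons = uorfStartCodons(),
                                length_range = c(6L, 300L)) {
  s <- normalizeSeq(tl_seq)
  n <- nchar(s)
  empty <- data.frame(tl_offset = integer(), length = integer(),
                      start_codon = character(), frame = integer(),
                      is_aug = logical(), stringsAsFactors = FALSE)
  if (n < max(6L, length_range[1])) return(empty)
  pat <- paste0("(?=(", paste(start_codons, collapse = "|"), "))")
  hit <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (hit[1] == -1) return(empty)
  starts <- as.integer(hit) # 1-based
  stops <- c("TAA", "TAG", "TGA")
  rows <- lapply(starts, function(st) {
    if (st + 3L > n - 2L) return(NULL)
    cod_starts <- seq(st + 3L, n - 2L, by = 3L)
    codons <- substring(s, cod_starts, cod_starts + 2L)
    stop_i <- which(codons %in% stops)
    if (!length(stop_i)) return(NULL)
    len <- stop_i[1] * 3L + 3L # start codon + body + stop codon
    if (len < length_range[1] || len > length_range[2]) return(NULL)
    codon <- substring(s, st, st + 2L)
    data.frame(tl_offset = st - 1L, length = len, start_codon = codon,
               frame = (n - (st - 1L)) %% 3L, is_aug = codon == "ATG",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Ribosome-profiling features of a uORF candidate
#'
#' Computed from one replicate's per-nucleotide TL coverage:
#' start-peak enrichment (mean coverage over the first two codons divided
#' by the TL-wide mean), body density (candidate mean over TL mean),
#' in-frame periodicity fraction (share of candidate coverage on frame-0
#' positions; 1/3 under uniform coverage), flank contrast (body mean over
#' the mean of 15-nt flanks), length and start-codon identity.
#'
#' @param candidate one row of \code{\link{enumerateCandidates}} output
#'   (list or data.frame row with tl_offset, length, is_aug).
#' @param coverage_track numeric vector of per-nucleotide coverage.
#' @return named numeric feature vector.
#' @export
extractFeatures <- function(candidate, coverage_track) {
  eps <- 0.01
  st <- candidate$tl_offset + 1L # 1-based
  en <- st + candidate$length - 1L
  body <- coverage_track[st:en]
  tl_mean <- mean(coverage_track)
  start_peak <- mean(coverage_track[st:min(en, st + 5L)]) / (tl_mean + eps)
  body_density <- mean(body) / (tl_mean + eps)
  tot <- sum(body)
  frame0 <- body[seq(1L, length(body), by = 3L)]
  inframe <- if (tot == 0) 1 / 3 else sum(frame0) / tot
  L <- length(coverage_track)
  up_idx <- if (st > 1L) max(1L, st - 15L):(st - 1L) else integer()
  down_idx <- if (en < L) (en + 1L):min(L, en + 15L) else integer()
  fl <- coverage_track[c(up_idx, down_idx)]
  # candidate spanning the whole TL has no flanks; fall back to TL mean
  flank_base <- if (length(fl)) mean(fl) else tl_mean
  flank_contrast <- mean(body) / (flank_base + eps)
  # initiation signatures: the footprint peak of a translated ORF sits
  # at its start codon, so (i) the start must rise above the immediate
  # upstream flank (kills starts nested inside a translated uORF) and
  # (ii) must not be quieter than the body (kills in-frame upstream
  # extensions that begin in background and run into a covered uORF)
  start_cov <- mean(coverage_track[st:min(en, st + 5L)])
  up <- if (st == 1L) 0 else coverage_track[max(1L, st - 6L):(st - 1L)]
  upstream_contrast <- start_cov / (mean(up) + eps)
  start_vs_body <- start_cov / (mean(body) + eps)
  c(start_peak = start_peak, body_density = body_density,
    inframe = inframe, flank_contrast = flank_contrast,
    upstream_contrast = upstream_contrast, start_vs_body = start_vs_body,
    length = candidate$length, is_aug = as.numeric(candidate$is_aug))
}

# curation score prior to classification: flank-normalized density
# weighted by frame preference (averaged over replicates)
rawUorfScore <- function(candidate, coverage) {
  sc <- vapply(seq_len(ncol(coverage)), function(r) {
    f <- extractFeatures(candidate, coverage[, r])
    f[["flank_contrast"]] * f[["inframe"]]
  }, 0)
  mean(sc)
}

# non-overlapping triplet partition starting at position 0; remainder
# (< 3 nt) stays in place
shuffleTriplets <- function(s, coverage, perm) {
  n <- nchar(s)
  nt <- n %/% 3L
  blocks <- split(seq_len(3L * nt), rep(seq_len(nt), each = 3L))
  idx <- c(unlist(blocks[perm], use.names = FALSE),
           if (3L * nt < n) (3L * nt + 1L):n)
  list(seq = paste(strsplit(s, "")[[1]][idx], collapse = ""),
       coverage = coverage[idx, , drop = FALSE])
}

#' Shuffled-triplet null for uORF scores
#'
#' Permutes each TL's non-overlapping nucleotide triplets (coverage
#' permuted in the same blocks, so the triplet multiset and the coverage
#' multiset are preserved), re-enumerates candidates on the shuffled
#' sequence and scores them. The null is kept per start-codon class (AUG
#' versus near-cognate); the configured quantile of each class defines
#' its curation threshold.
#'
#' @param tl_seq TL sequence.
#' @param coverage length x replicates coverage matrix.
#' @param n_shuffles number of triplet permutations.
#' @param seed integer seed.
#' @param start_codons,length_range as in
#'   \code{\link{enumerateCandidates}}.
#' @return data.frame of null scores: start_class ("AUG"/"near"), score.
#' @export
tripletShuffleNull <- function(tl_seq, coverage, n_shuffles = 20,
                               seed = 1L,
                               start_codons = uorfStartCodons(),
                               length_range = c(6L, 300L)) {
  nullSamples(tl_seq, coverage, n_shuffles, seed, start_codons,
              length_range)$scores
}

# shuffled-triplet null scores plus the per-replicate feature vectors of
# the null candidates (the sub-threshold ones later serve as decoys)
nullSamples <- function(tl_seq, coverage, n_shuffles, seed,
                        start_codons = uorfStartCodons(),
                        length_range = c(6L, 300L)) {
  s <- normalizeSeq(tl_seq)
  nt <- nchar(s) %/% 3L
  empty <- list(scores = data.frame(start_class = character(),
                                    score = numeric()),
                features = NULL)
  if (nt < 2L) return(empty)
  set.seed(seed)
  n_reps <- ncol(coverage)
  out <- vector("list", n_shuffles)
  feats <- vector("list", n_shuffles)
  for (i in seq_len(n_shuffles)) {
    sh <- shuffleTriplets(s, coverage, sample.int(nt))
    cand <- enumerateCandidates(sh$seq, start_codons, length_range)
    if (!nrow(cand)) next
    # features per replicate; the raw score is the replicate mean of
    # flank contrast x in-frame fraction, as for real candidates
    f_rep <- lapply(seq_len(n_reps), function(r) {
      t(vapply(seq_len(nrow(cand)), function(j) {
        extractFeatures(cand[j, ], sh$coverage[, r])
      }, numeric(8)))
    })
    sc_m <- vapply(f_rep, function(f) {
      f[, "flank_contrast"] * f[, "inframe"]
    }, numeric(nrow(cand)))
    sc <- if (is.matrix(sc_m)) rowMeans(sc_m) else mean(sc_m)
    out[[i]] <- data.frame(
      start_class = ifelse(cand$is_aug, "AUG", "near"), score = sc,
      stringsAsFactors = FALSE)
    feats[[i]] <- f_rep
  }
  keep <- !vapply(out, is.null, TRUE)
  if (!any(keep)) return(empty)
  features <- lapply(seq_len(n_reps), function(r) {
    do.call(rbind, lapply(feats[keep], `[[`, r))
  })
  list(scores = do.call(rbind, out[keep]), features = features)
}

# fit one per-replicate classifier and return scores in [0, 1]
fitReplicateClassifier <- function(features, labels, newdata, classifier,
                                   seed) {
  df <- as.data.frame(features)
  df$y <- labels
  nd <- as.data.frame(newdata)
  if (classifier == "mlp") {
    set.seed(seed)
    fit <- nnet::nnet(y ~ ., data = df, size = 4, decay = 0.01,
                      maxit = 300, trace = FALSE, entropy = TRUE)
    as.numeric(predict(fit, nd))
  } else {
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    as.numeric(suppressWarnings(predict(fit, nd, type = "response")))
  }
}

#' Train per-replicate classifiers and call high-confidence uORFs
#'
#' Curated positives and sub-threshold decoys train one classifier per
#' ribosome-profiling replicate on that replicate's features. A candidate
#' is called in a replicate when its score strictly exceeds 0.5;
#' high-confidence uORFs are those called independently in every
#' replicate.
#'
#' @param candidates data.frame of candidates with columns gene_id,
#'   tl_offset, length, start_codon, is_aug.
#' @param positives logical vector marking curated positive candidates.
#' @param decoys logical vector marking decoy (negative) candidates.
#' @param coverage named list of length x replicates coverage matrices.
#' @param config \code{\link{pipelineConfig}}.
#' @param null_decoy_features optional list (one matrix per replicate) of
#'   feature vectors of sub-threshold candidates from the shuffled-TL
#'   null, added to the decoy side of the training set.
#' @return candidates with per-replicate score columns
#'   (\code{score_rep<k>}), \code{called_rep<k>} and
#'   \code{high_confidence}.
#' @export
trainAndCall <- function(candidates, positives, decoys, coverage, config,
                         null_decoy_features = NULL) {
  stopifnot(nrow(candidates) == length(positives),
            nrow(candidates) == length(decoys))
  if (sum(positives) < 20) {
    stop("need >= 20 curated positive uORFs to train")
  }
  n_pos <- sum(positives)
  if (sum(decoys) > 50 * n_pos) {
    warning("decoy imbalance > 50:1; downsampling decoys")
    set.seed(config$rng_seed)
    keep <- sample(which(decoys), 50 * n_pos)
    decoys <- seq_along(decoys) %in% keep
  }
  n_reps <- ncol(coverage[[1]])
  featureMatrix <- function(rep) {
    t(vapply(seq_len(nrow(candidates)), function(i) {
      extractFeatures(candidates[i, ],
                      coverage[[candidates$gene_id[i]]][, rep])
    }, numeric(8)))
  }
  # cap the shuffled-null decoys at 25:1 against the positives
  null_idx <- NULL
  if (!is.null(null_decoy_features) && nrow(null_decoy_features[[1]])) {
    n_null <- nrow(null_decoy_features[[1]])
    set.seed(config$rng_seed + 1L)
    null_idx <- if (n_null > 25 * n_pos) sample.int(n_null, 25 * n_pos)
                else seq_len(n_null)
  }
  train_idx <- which(positives | decoys)
  labels <- as.numeric(positives[train_idx])
  out <- candidates
  called <- matrix(FALSE, nrow(candidates), n_reps)
  for (r in seq_len(n_reps)) {
    fm <- featureMatrix(r)
    train_fm <- fm[train_idx, , drop = FALSE]
    train_lab <- labels
    if (!is.null(null_idx)) {
      train_fm <- rbind(train_fm,
                        null_decoy_features[[r]][null_idx, , drop = FALSE])
      train_lab <- c(train_lab, rep(0, length(null_idx)))
    }
    scores <- fitReplicateClassifier(
      train_fm, train_lab, fm, config$classifier, config$rng_seed + r)
    out[[paste0("score_rep", r)]] <- scores
    called[, r] <- scores > 0.5
    out[[paste0("called_rep", r)]] <- called[, r]
  }
  out$high_confidence <- rowSums(called) == n_reps
  out
}

#' Full uORF calling pipeline over a set of TLs
#'
#' Enumerates candidates in every TL, builds the shuffled-triplet null
#' per start-codon class, curates the supplied validated uORFs (those
#' scoring above the class null quantile), draws decoys from
#' sub-threshold non-validated candidates, trains per-replicate
#' classifiers and intersects replicate calls.
#'
#' @param tls named DNAStringSet (or character vector) of TL sequences.
#' @param coverage named list of length x replicates coverage matrices.
#' @param validated data.frame of validated uORFs: gene_id, tl_offset,
#'   length (the training compendium; in synthetic runs, planted truth).
#' @param config \code{\link{pipelineConfig}}.
#' @return list: \code{candidates} (scored data.frame with
#'   high_confidence flags), \code{null_thresholds} (per start class),
#'   \code{curated} (curated positive key set).
#' @export
callUorfs <- function(tls, coverage, validated, config = pipelineConfig()) {
  tls <- vapply(as.character(tls), normalizeSeq, "")
  genes <- names(tls)
  cand <- do.call(rbind, lapply(genes, function(g) {
    cc <- enumerateCandidates(tls[[g]], length_range = config$uorf_length_range)
    if (nrow(cc)) cbind(gene_id = g, cc, stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(cand) || !nrow(cand)) stop("no uORF candidates found")
  cand$raw_score <- vapply(seq_len(nrow(cand)), function(i) {
    rawUorfScore(cand[i, ], coverage[[cand$gene_id[i]]])
  }, 0)

  # accumulate null scores over TLs in seeded random order; stop once both
  # start-codon classes are well sampled (the null is pooled across TLs)
  set.seed(config$rng_seed)
  gene_order <- sample(seq_along(genes))
  acc <- list()
  acc_feat <- list()
  n_aug <- 0L
  n_near <- 0L
  for (gi in gene_order) {
    g <- genes[gi]
    ns <- nullSamples(tls[[g]], coverage[[g]],
                      n_shuffles = config$n_shuffles,
                      seed = config$rng_seed + gi,
                      length_range = config$uorf_length_range)
    if (nrow(ns$scores)) {
      acc[[length(acc) + 1L]] <- ns$scores
      acc_feat[[length(acc_feat) + 1L]] <- ns$features
      n_aug <- n_aug + sum(ns$scores$start_class == "AUG")
      n_near <- n_near + sum(ns$scores$start_class == "near")
    }
    if (n_aug >= 3000L && n_near >= 3000L) break
  }
  nulls <- do.call(rbind, acc)
  thr <- vapply(c(AUG = "AUG", near = "near"), function(cl) {
    x <- nulls$score[nulls$start_class == cl]
    if (!length(x)) Inf else as.numeric(quantile(x, config$null_quantile))
  }, 0)

  key <- function(g, o) paste(g, o, sep = "@")
  vkey <- key(validated$gene_id, validated$tl_offset)
  ckey <- key(cand$gene_id, cand$tl_offset)
  is_validated <- ckey %in% vkey
  class_thr <- thr[ifelse(cand$is_aug, "AUG", "near")]
  positives <- is_validated & cand$raw_score > class_thr
  decoys <- !is_validated & cand$raw_score <= class_thr

  # sub-threshold candidates from the shuffled TLs are additional decoys:
  # shuffling scatters real signal into incoherent mid-density patterns,
  # which is the negative space the classifier must learn to reject
  n_reps <- ncol(coverage[[1]])
  null_thr <- thr[ifelse(nulls$start_class == "AUG", "AUG", "near")]
  sub <- nulls$score <= null_thr
  null_features <- lapply(seq_len(n_reps), function(r) {
    do.call(rbind, lapply(acc_feat, `[[`, r))[sub, , drop = FALSE]
  })

  scored <- trainAndCall(cand, positives, decoys, coverage, config,
                         null_decoy_features = null_features)
  scored$curated <- positives
  list(candidates = scored, null_thresholds = thr,
       curated = ckey[positives])
}
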