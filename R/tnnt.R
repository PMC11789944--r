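#' @importFrom stats lm rstandard coef
NULL

#' Gaussian-GLM outlier test on untransformed abundances
#'
#' Fits an ordinary Gaussian linear model of the evolved response level
#' on the full factorial expansion (main effects, all pairwise and the
#' three-way interaction) of three covariates: the evolved prior level
#' and the ancestor's level and prior level. Because the model is scale
#' agnostic, it can be fit to untransformed values even when response and
#' predictors live on very different numerical scales. Genes whose
#' leverage-adjusted standardized residual strictly exceeds the threshold
#' in absolute value are flagged, signed by residual direction.
#'
#' @param response evolved-strain abundance at the tested level
#'   (per-gene medians, untransformed).
#' @param evolved_prior evolved abundance at the preceding level.
#' @param ancestor_level,ancestor_prior the ancestor's abundances at the
#'   tested and preceding levels.
#' @param threshold standardized-residual cutoff (strict inequality).
#' @return data.frame: gene_id (names of response, if any),
#'   standardized_residual, flagged, direction.
#' @export
glmOutlier <- function(response, evolved_prior, ancestor_level,
                       ancestor_prior, threshold = 1.96) {
  df <- data.frame(y = response, ep = evolved_prior,
                   al = ancestor_level, ap = ancestor_prior)
  fit <- lm(y ~ ep * al * ap, data = df)
  if (anyNA(coef(fit))) {
    warning("rank-deficient design: aliased terms dropped")
  }
  r <- rstandard(fit)
  # an (essentially) exact fit leaves only numerical noise: no outliers
  sigma <- suppressWarnings(summary(fit)$sigma)
  if (sigma < 1e-8 * max(sd(response), .Machine$double.eps)) {
    r <- rep(0, length(response))
  }
  flagged <- abs(r) > threshold
  data.frame(
    gene_id = if (is.null(names(response))) seq_along(response) else names(response),
    standardized_residual = as.numeric(r),
    flagged = flagged,
    direction = ifelse(!flagged, "none", ifelse(r > 0, "higher", "lower")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Transformed near-neighbor test (TNNT)
#'
#' Scale-independent outlier test on Box-Cox + MinMax transformed
#' efficiency ratios. Genes are ranked by the distance between the
#' evolved and ancestral efficiencies (absolute difference, descending);
#' each gene is scored by the ratio evolved/ancestor. A neighborhood of
#' the nearest \code{neighborhood_fraction} of genes in rank order is
#' subsampled (with replacement) \code{n_permutations} times, counting
#' the fraction of sampled genes whose score meets or exceeds the focal
#' score in the focal gene's direction (>= for score > 1, <= for
#' score < 1). The mean exceedance fraction is the empirical FDR. A gene
#' is disqualified when its within-strain replicate range exceeds the
#' between-strain distance.
#'
#' @param evolved_eff,ancestor_eff transformed efficiency ratios
#'   (per-gene, both in (0, 1]-derived units), named by gene.
#' @param replicate_range per-gene within-strain replicate range of the
#'   transformed efficiency ratio (max over the two strains); NULL
#'   disables the variance filter.
#' @param config \code{\link{pipelineConfig}} (neighborhood fraction,
#'   permutations, subsample size, alpha, seed).
#' @return data.frame: gene_id, distance, distance_rank, score, fdr,
#'   variance_filtered, call.
#' @export
tnnt <- function(evolved_eff, ancestor_eff, replicate_range = NULL,
                 config = pipelineConfig()) {
  n <- length(evolved_eff)
  if (n < 20) stop("TNNT needs >= 20 genes (neighborhood degenerate)")
  stopifnot(length(ancestor_eff) == n)
  gene_id <- names(evolved_eff)
  if (is.null(gene_id)) gene_id <- as.character(seq_len(n))

  distance <- abs(evolved_eff - ancestor_eff)
  score <- evolved_eff / ancestor_eff
  ord <- order(distance, decreasing = TRUE)
  rank_pos <- integer(n)
  rank_pos[ord] <- seq_len(n) # 1 = largest distance
  score_by_rank <- score[ord]

  k <- max(2L, round(config$neighborhood_fraction * n))
  m <- min(config$subsample_size, k)
  nperm <- config$n_permutations

  set.seed(config$rng_seed)
  fdr <- numeric(n)
  for (i in seq_len(n)) {
    pos <- rank_pos[i]
    lo <- pos - k %/% 2L
    hi <- lo + k # window of k+1 ranks containing the focal
    if (lo < 1L) { hi <- hi + (1L - lo); lo <- 1L }
    if (hi > n) { lo <- lo - (hi - n); hi <- n }
    nb <- score_by_rank[lo:hi][setdiff(seq_len(hi - lo + 1L), pos - lo + 1L)]
    draws <- matrix(sample(nb, m * nperm, replace = TRUE), nrow = nperm)
    s <- score[i]
    exceed <- if (s >= 1) draws >= s else draws <= s
    fdr[i] <- mean(rowMeans(exceed))
  }

  variance_filtered <- if (is.null(replicate_range)) {
    rep(FALSE, n)
  } else {
    !is.na(replicate_range) & replicate_range > distance
  }
  call <- rep("none", n)
  sig <- fdr < config$alpha & !variance_filtered
  call[sig & score > 1] <- "higher"
  call[sig & score < 1] <- "lower"
  data.frame(
    gene_id = gene_id, distance = distance, distance_rank = rank_pos,
    score = score, fdr = fdr, variance_filtered = variance_filtered,
    call = call, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Additive combination of TNNT and the GLM outlier test (TNNTg)
#'
#' A gene is called when TNNT calls it (FDR < alpha) or the GLM flags it.
#' Direction comes from the agreeing method; when both fire with
#' conflicting signs the TNNT direction wins and the conflict is flagged.
#'
#' @param tnnt_result output of \code{\link{tnnt}}.
#' @param glm_result output of \code{\link{glmOutlier}} on the same genes
#'   (same order).
#' @return data.frame: gene_id, tnnt_call, glm_direction, call,
#'   direction_conflict.
#' @export
tnntg <- function(tnnt_result, glm_result) {
  stopifnot(nrow(tnnt_result) == nrow(glm_result))
  tc <- tnnt_result$call
  gc_ <- glm_result$direction
  call <- ifelse(tc != "none", tc, gc_)
  conflict <- tc != "none" & gc_ != "none" & tc != gc_
  data.frame(
    gene_id = tnnt_result$gene_id,
    tnnt_call = tc, glm_direction = gc_,
    call = call, direction_conflict = conflict,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Confusion-matrix benchmark of calls against ground truth
#'
#' @param calls logical vector (or call strings where "none" is negative).
#' @param truth logical vector of true effect labels.
#' @return list: tp, fp, fn, tn, precision, recall, fpr, fnr, f1. F1 is
#'   NA when the truth has no positives; 0 when there are positives but
#'   no true-positive calls.
#' @export
benchmarkCalls <- function(calls, truth) {
  if (is.character(calls)) calls <- calls != "none"
  stopifnot(length(calls) == length(truth))
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  fn <- sum(!calls & truth)
  tn <- sum(!calls & !truth)
  if (tp + fn == 0) {
    return(list(tp = tp, fp = fp, fn = fn, tn = tn,
                precision = NA_real_, recall = NA_real_,
                fpr = fp / (fp + tn), fnr = NA_real_, f1 = NA_real_))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall,
       fpr = fp / (fp + tn), fnr = fn / (fn + tp), f1 = f1)
}

#' Scale-independent efficiency outlier analysis for one strain
#'
#' End-to-end runner for one level pair: summarizes replicates, fits the
#' Box-Cox + MinMax transform jointly on the pooled ancestor + evolved
#' medians of each level, forms transformed efficiency ratios, applies
#' TNNT (with the replicate-range variance filter) and the GLM outlier
#' test on untransformed medians, and combines them as TNNTg.
#'
#' @param moe MultiOmicsExperiment (already QC-filtered, no missing MS).
#' @param strain evolved strain.
#' @param level_pair "MS/RPF" (protein expression efficiency) or
#'   "RPF/RNA" (translation efficiency).
#' @param config \code{\link{pipelineConfig}}.
#' @return data.frame combining TNNT, GLM and TNNTg columns per gene.
#' @export
efficiencyOutliers <- function(moe, strain, level_pair = c("MS/RPF", "RPF/RNA"),
                               config = pipelineConfig()) {
  level_pair <- match.arg(level_pair)
  parts <- strsplit(level_pair, "/", fixed = TRUE)[[1]]
  anc <- ancestorStrain(moe)

  prep <- function(level) {
    m <- levelValues(moe, level)
    if (level %in% c("RNA", "RPF")) {
      m <- tpm(m, geneData(moe)$cds_length)
    }
    smp <- levelSamples(moe, level)
    evo <- summarizeReplicates(m, smp, strain)
    an <- summarizeReplicates(m, smp, anc)
    # one monotone scale shared by both strains: fit on pooled medians
    fit <- boxCoxMinMax(c(evo$median, an$median))
    reps_evo <- m[, smp$strain == strain, drop = FALSE]
    reps_anc <- m[, smp$strain == anc, drop = FALSE]
    list(
      evo_median = evo$median, anc_median = an$median,
      t_evo = applyTransform(evo$median, fit$record),
      t_anc = applyTransform(an$median, fit$record),
      t_reps_evo = applyTransform(reps_evo, fit$record),
      t_reps_anc = applyTransform(reps_anc, fit$record),
      record = fit$record
    )
  }
  num <- prep(parts[1])
  den <- prep(parts[2])

  eff_evo <- num$t_evo / den$t_evo
  eff_anc <- num$t_anc / den$t_anc
  names(eff_evo) <- geneData(moe)$gene_id

  ratioRange <- function(nreps, dreps) {
    r <- min(ncol(nreps), ncol(dreps))
    ratios <- nreps[, seq_len(r), drop = FALSE] / dreps[, seq_len(r), drop = FALSE]
    apply(ratios, 1, function(x) max(x) - min(x))
  }
  rng <- pmax(ratioRange(num$t_reps_evo, den$t_reps_evo),
              ratioRange(num$t_reps_anc, den$t_reps_anc))

  tn <- tnnt(eff_evo, eff_anc, rng, config)
  gl <- glmOutlier(num$evo_median, den$evo_median,
                   num$anc_median, den$anc_median,
                   threshold = config$glm_residual_threshold)
  comb <- tnntg(tn, gl)
  data.frame(
    gene_id = geneData(moe)$gene_id, strain = strain,
    level_pair = level_pair,
    evolved_eff = eff_evo, ancestor_eff = eff_anc,
    distance = tn$distance, score = tn$score, fdr = tn$fdr,
    variance_filtered = tn$variance_filtered,
    tnnt_call = tn$call,
    glm_standardized_residual = gl$standardized_residual,
    glm_direction = gl$direction,
    call = comb$call, direction_conflict = comb$direction_conflict,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
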