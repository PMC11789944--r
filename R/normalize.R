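#' @importFrom stats optimize sd var
NULL

#' QC filter on the shared gene universe
#'
#' Retains genes that (i) are not transposon associated, (ii) have at
#' least \code{min_rna_reads} RNA reads and \code{min_rpf_reads} RPFs in
#' every strain (summed over replicates, thresholds inclusive), and
#' (iii) are detected by MS (non-missing in a majority of MS replicates
#' of every strain) when \code{require_ms_detection} is on. Breakpoint
#' disruption is strain specific, so it is reported as per-strain
#' exclusions rather than removal from the shared set.
#'
#' @param moe MultiOmicsExperiment.
#' @param config \code{\link{pipelineConfig}}.
#' @return list: \code{retained} gene ids, \code{per_strain_excluded}
#'   (named list of disrupted gene ids per strain) and \code{reasons}
#'   data.frame for removed genes.
#' @export
qcFilter <- function(moe, config = pipelineConfig()) {
  gd <- geneData(moe)
  ids <- gd$gene_id
  strains <- strainNames(moe)

  strainSums <- function(level) {
    m <- levelValues(moe, level)
    st <- levelSamples(moe, level)$strain
    sapply(strains, function(s) rowSums(m[, st == s, drop = FALSE]))
  }
  rna_ok <- apply(strainSums("RNA") >= config$min_rna_reads, 1, all)
  rpf_ok <- apply(strainSums("RPF") >= config$min_rpf_reads, 1, all)

  ms_ok <- rep(TRUE, length(ids))
  if (config$require_ms_detection) {
    m <- msIntensities(moe)
    st <- levelSamples(moe, "MS")$strain
    det <- sapply(strains, function(s) {
      sub <- m[, st == s, drop = FALSE]
      rowSums(!is.na(sub)) > ncol(sub) / 2
    })
    ms_ok <- apply(det, 1, all)
  }
  tn_ok <- !gd$transposon_associated

  keep <- rna_ok & rpf_ok & ms_ok & tn_ok
  if (!any(keep)) stop("QC removed every gene")
  reasons <- data.frame(
    gene_id = ids[!keep],
    low_rna = !rna_ok[!keep], low_rpf = !rpf_ok[!keep],
    ms_undetected = !ms_ok[!keep], transposon = !tn_ok[!keep]
  )
  dis <- disruptedGenes(moe)
  per_strain <- lapply(setdiff(strains, ancestorStrain(moe)), function(s) {
    ids[dis[, s] & keep]
  })
  names(per_strain) <- setdiff(strains, ancestorStrain(moe))
  list(retained = ids[keep], per_strain_excluded = per_strain,
       reasons = reasons)
}

#' Transcripts-per-million normalization
#'
#' Per sample: length-normalized rate count/length, rescaled so each
#' column sums to one million.
#'
#' @param counts genes x samples matrix.
#' @param lengths per-gene CDS lengths (nt), positive.
#' @return TPM matrix of the same shape.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("all-zero sample in TPM normalization")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Summarize replicates of one strain
#'
#' Elementwise median across the strain's replicate columns, plus the
#' replicate range (max - min) per gene used by the TNNT variance filter.
#' MS "not detected" values are dropped per gene before summarizing.
#'
#' @param m genes x samples matrix.
#' @param samples data.frame with a \code{strain} column aligned to the
#'   columns of \code{m}.
#' @param strain strain to summarize.
#' @return list: \code{median} and \code{range} vectors.
#' @export
summarizeReplicates <- function(m, samples, strain) {
  sub <- m[, samples$strain == strain, drop = FALSE]
  if (ncol(sub) < 2) stop("need >= 2 replicates for ", strain)
  med <- apply(sub, 1, median, na.rm = TRUE)
  rng <- apply(sub, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else max(x) - min(x)
  })
  list(median = med, range = rng)
}

# Box-Cox transform of positive values at fixed lambda
bcTransform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

bcInverse <- function(y, lambda) {
  if (abs(lambda) < 1e-12) exp(y) else (lambda * y + 1)^(1 / lambda)
}

#' Box-Cox + MinMax transform to (epsilon, 1]
#'
#' Fits the Box-Cox exponent by maximum likelihood (profile likelihood of
#' the normal model), then MinMax-rescales to \code{(epsilon, 1]} so all
#' outputs are strictly positive and the maximum maps to exactly 1. Zeros
#' in the input trigger a +1 pseudo-offset before the power transform.
#' The fitted transform is strictly increasing, so ranks are preserved
#' and it is exactly invertible.
#'
#' @param values non-negative numeric vector (NAs allowed, passed through).
#' @param epsilon lower bound of the output range.
#' @param lambda_range search interval for the exponent.
#' @return list: \code{values} (transformed) and \code{record}
#'   (\linkS4class{BoxCoxTransform}).
#' @export
boxCoxMinMax <- function(values, epsilon = 1e-6, lambda_range = c(-2, 2)) {
  ok <- !is.na(values)
  x <- values[ok]
  if (any(x < 0)) stop("negative values in boxCoxMinMax")
  if (length(unique(x)) < 2) stop("degenerate input: constant values")
  offset <- if (any(x == 0)) 1 else 0
  x <- x + offset
  slx <- sum(log(x))
  n <- length(x)
  profile_ll <- function(lambda) {
    y <- bcTransform(x, lambda)
    -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * slx
  }
  lambda <- optimize(profile_ll, lambda_range, maximum = TRUE)$maximum
  y <- bcTransform(x, lambda)
  rec <- new("BoxCoxTransform", lambda = lambda, offset = offset,
             bcMin = min(y), bcMax = max(y), epsilon = epsilon)
  out <- values
  out[ok] <- applyTransform(values[ok], rec)
  list(values = out, record = rec)
}

#' Apply a fitted Box-Cox + MinMax transform to new values
#' @param values numeric vector on the original scale.
#' @param record BoxCoxTransform from \code{\link{boxCoxMinMax}}.
#' @return transformed values; values beyond the fitted range map beyond
#'   (epsilon, 1] monotonically.
#' @export
applyTransform <- function(values, record) {
  y <- bcTransform(values + record@offset, record@lambda)
  (y - record@bcMin) / (record@bcMax - record@bcMin) *
    (1 - record@epsilon) + record@epsilon
}

#' Invert a Box-Cox + MinMax transform
#' @param values transformed values in (epsilon, 1].
#' @param record BoxCoxTransform.
#' @return values on the original scale.
#' @export
invertTransform <- function(values, record) {
  y <- (values - record@epsilon) / (1 - record@epsilon) *
    (record@bcMax - record@bcMin) + record@bcMin
  bcInverse(y, record@lambda) - record@offset
}

#' Serialize a transform record to JSON
#' @param record BoxCoxTransform.
#' @param path output path.
#' @export
writeTransformRecord <- function(record, path) {
  jsonlite::write_json(
    list(lambda = record@lambda, offset = record@offset,
         bc_min = record@bcMin, bc_max = record@bcMax,
         epsilon = record@epsilon),
    path, auto_unbox = TRUE, digits = NA)
}
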