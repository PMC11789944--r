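#' Pipeline configuration
#'
#' Central bundle of thresholds and tuning parameters used across the
#' pipeline stages. Defaults follow the study design: genes must have at
#' least 100 aligned RNA reads and 10 RPFs in every strain and be detected
#' by MS to pass QC; near-neighbor outlier calls use the nearest 10% of
#' genes, 5 permutations and FDR < 0.05; GLM outliers use |standardized
#' residual| > 1.96; uORFs are 6-300 nt with a 95th-percentile
#' shuffled-triplet null threshold.
#'
#' @param min_rna_reads minimum RNA reads per strain (summed over
#'   replicates) for a gene to pass QC.
#' @param min_rpf_reads minimum RPF reads per strain.
#' @param require_ms_detection drop genes not detected by MS.
#' @param alpha significance level for every test family (BH-adjusted
#'   where applicable).
#' @param neighborhood_fraction fraction of genes forming the TNNT rank
#'   neighborhood.
#' @param n_permutations number of TNNT neighborhood subsamples per gene.
#' @param subsample_size TNNT subsample size (capped at neighborhood size).
#' @param glm_residual_threshold standardized-residual cutoff for the GLM
#'   outlier test (strict inequality).
#' @param uorf_length_range allowed uORF lengths in nucleotides (inclusive).
#' @param null_quantile quantile of the shuffled-triplet null used as the
#'   uORF curation threshold.
#' @param n_shuffles shuffles per TL when building the uORF null.
#' @param classifier "mlp" (single-hidden-layer neural net) or "logistic".
#' @param motif degenerate Ssd1 binding motif (RNA alphabet; U and T are
#'   interchangeable).
#' @param library_size_normalize scale RNA/RPF counts to a common library
#'   size before the expected-count construction (off by default; the
#'   expected counts are built from unnormalized reads).
#' @param rng_seed integer seed consumed by every stochastic stage.
#' @return A list of class \code{cnveff_config}.
#' @export
pipelineConfig <- function(min_rna_reads = 100,
                           min_rpf_reads = 10,
                           require_ms_detection = TRUE,
                           alpha = 0.05,
                           neighborhood_fraction = 0.10,
                           n_permutations = 5,
                           subsample_size = 100,
                           glm_residual_threshold = 1.96,
                           uorf_length_range = c(6L, 300L),
                           null_quantile = 0.95,
                           n_shuffles = 20,
                           classifier = c("mlp", "logistic"),
                           motif = "CNYUCNYU",
                           library_size_normalize = FALSE,
                           rng_seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(
    min_rna_reads > 0, min_rpf_reads > 0,
    alpha > 0, alpha < 1,
    neighborhood_fraction > 0, neighborhood_fraction < 1,
    n_permutations >= 1, subsample_size >= 1,
    glm_residual_threshold > 0,
    length(uorf_length_range) == 2L,
    uorf_length_range[1] >= 3, uorf_length_range[2] >= uorf_length_range[1],
    null_quantile > 0, null_quantile < 1, n_shuffles >= 1
  )
  structure(
    list(min_rna_reads = min_rna_reads,
         min_rpf_reads = min_rpf_reads,
         require_ms_detection = require_ms_detection,
         alpha = alpha,
         neighborhood_fraction = neighborhood_fraction,
         n_permutations = n_permutations,
         subsample_size = subsample_size,
         glm_residual_threshold = glm_residual_threshold,
         uorf_length_range = as.integer(uorf_length_range),
         null_quantile = null_quantile,
         n_shuffles = n_shuffles,
         classifier = classifier,
         motif = motif,
         library_size_normalize = library_size_normalize,
         rng_seed = as.integer(rng_seed)),
    class = "cnveff_config"
  )
}
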