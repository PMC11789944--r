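#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Container for one multi-omic chemostat experiment
#'
#' Holds the three measurement levels of a CNV gene-expression study --
#' RNA-seq counts, ribosome-profiling (RPF) counts and mass-spectrometry
#' (MS) intensities -- as \linkS4class{SummarizedExperiment} objects over a
#' shared gene universe, together with gene annotation (coordinates, CDS
#' length, transcript-leader interval), per-strain copy numbers and
#' breakpoint-disruption flags.
#'
#' RNA and RPF assays store non-negative integer counts; the MS assay
#' stores non-negative real intensities with \code{NA} meaning "not
#' detected" (a distinct missing state, never imputed as zero). Each
#' level's \code{colData} has columns \code{strain} and \code{replicate}.
#'
#' @slot rna SummarizedExperiment of RNA-seq counts (genes x samples).
#' @slot rpf SummarizedExperiment of RPF counts.
#' @slot ms SummarizedExperiment of MS intensities.
#' @slot geneData DataFrame with one row per gene: \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   \code{strand}, \code{cds_length}, \code{tl_start}, \code{tl_end}
#'   (NA when no transcript leader is annotated),
#'   \code{transposon_associated}.
#' @slot copyNumber integer matrix genes x strains.
#' @slot disrupted logical matrix genes x strains; TRUE when a CNV
#'   breakpoint disrupts the gene in that strain.
#' @slot ancestor character(1), name of the ancestral strain.
#'
#' @export
setClass("MultiOmicsExperiment",
  slots = c(
    rna = "SummarizedExperiment",
    rpf = "SummarizedExperiment",
    ms = "SummarizedExperiment",
    geneData = "DataFrame",
    copyNumber = "matrix",
    disrupted = "matrix",
    ancestor = "character"
  )
)

setValidity("MultiOmicsExperiment", function(object) {
  msg <- character()
  ids <- object@geneData$gene_id
  if (is.null(ids)) {
    return("geneData must have a gene_id column")
  }
  if (anyDuplicated(ids)) {
    msg <- c(msg, "duplicate gene_id in geneData")
  }
  for (lv in c("rna", "rpf", "ms")) {
    se <- slot(object, lv)
    if (!identical(rownames(se), ids)) {
      msg <- c(msg, sprintf("%s rownames do not match geneData gene_id", lv))
    }
    cd <- colData(se)
    if (!all(c("strain", "replicate") %in% colnames(cd))) {
      msg <- c(msg, sprintf("%s colData needs strain and replicate", lv))
    }
  }
  for (lv in c("rna", "rpf")) {
    x <- assay(slot(object, lv))
    if (any(x < 0, na.rm = TRUE) || any(x != round(x), na.rm = TRUE)) {
      msg <- c(msg, sprintf("%s counts must be non-negative integers", lv))
    }
  }
  if (any(assay(object@ms) < 0, na.rm = TRUE)) {
    msg <- c(msg, "ms intensities must be non-negative")
  }
  if (!identical(rownames(object@copyNumber), ids)) {
    msg <- c(msg, "copyNumber rownames must match gene_id")
  }
  if (any(object@copyNumber < 1)) {
    msg <- c(msg, "copy numbers must be >= 1")
  }
  if (!identical(dim(object@disrupted), dim(object@copyNumber))) {
    msg <- c(msg, "disrupted must have the same shape as copyNumber")
  }
  if (length(object@ancestor) != 1L ||
      !(object@ancestor %in% colnames(object@copyNumber))) {
    msg <- c(msg, "ancestor must name a column of copyNumber")
  }
  strains <- colnames(object@copyNumber)
  for (lv in c("rna", "rpf", "ms")) {
    st <- colData(slot(object, lv))$strain
    if (!all(st %in% strains)) {
      msg <- c(msg, sprintf("%s has samples from strains absent in copyNumber", lv))
    }
    if (any(table(st) < 2L)) {
      msg <- c(msg, sprintf("every strain needs >= 2 %s replicates", lv))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Monotone Box-Cox + MinMax transform record
#'
#' Stores the fitted Box-Cox exponent and the MinMax bounds so a transform
#' can be re-applied to new values (e.g. replicate-level data) and inverted
#' exactly. The forward map is
#' \code{minmax(boxcox(x + offset, lambda))} rescaled to \code{(epsilon, 1]}.
#'
#' @slot lambda numeric(1) Box-Cox exponent fitted by maximum likelihood.
#' @slot offset numeric(1) pseudo-offset added before the power transform
#'   (1 when the input contained zeros, else 0).
#' @slot bcMin,bcMax numeric(1) Box-Cox-scale bounds used by MinMax.
#' @slot epsilon numeric(1) lower bound of the output range.
#' @export
setClass("BoxCoxTransform",
  slots = c(
    lambda = "numeric", offset = "numeric",
    bcMin = "numeric", bcMax = "numeric", epsilon = "numeric"
  )
)

setValidity("BoxCoxTransform", function(object) {
  if (object@bcMax <= object@bcMin) {
    return("degenerate transform: bcMax <= bcMin")
  }
  if (object@epsilon <= 0 || object@epsilon >= 1) {
    return("epsilon must lie in (0, 1)")
  }
  TRUE
})
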