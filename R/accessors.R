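#' @include AllClasses.R
NULL

#' Construct a MultiOmicsExperiment
#'
#' @param rna,rpf,ms SummarizedExperiments (or matrices plus sample tables,
#'   see \code{makeLevelSE}) for the three measurement levels.
#' @param geneData DataFrame or data.frame of gene annotation (see class
#'   documentation for required columns).
#' @param copyNumber integer matrix genes x strains.
#' @param disrupted logical matrix genes x strains; defaults to all FALSE.
#' @param ancestor character(1) ancestral strain name.
#' @return A \linkS4class{MultiOmicsExperiment}.
#' @export
MultiOmicsExperiment <- function(rna, rpf, ms, geneData, copyNumber,
                                 disrupted = NULL, ancestor) {
  geneData <- as(geneData, "DataFrame")
  if (is.null(disrupted)) {
    disrupted <- matrix(FALSE, nrow(copyNumber), ncol(copyNumber),
                        dimnames = dimnames(copyNumber))
  }
  storage.mode(copyNumber) <- "integer"
  new("MultiOmicsExperiment",
      rna = rna, rpf = rpf, ms = ms, geneData = geneData,
      copyNumber = copyNumber, disrupted = disrupted, ancestor = ancestor)
}

#' Build a per-level SummarizedExperiment from a matrix
#'
#' @param values genes x samples matrix; column names "strain:replicate".
#' @param strain,replicate optional explicit sample annotations; parsed
#'   from column names when missing.
#' @return SummarizedExperiment with strain/replicate colData.
#' @export
makeLevelSE <- function(values, strain = NULL, replicate = NULL) {
  if (is.null(strain)) {
    parts <- strsplit(colnames(values), ":", fixed = TRUE)
    strain <- vapply(parts, `[`, "", 1L)
    replicate <- as.integer(vapply(parts, `[`, "", 2L))
  }
  SummarizedExperiment(
    assays = list(values = values),
    colData = DataFrame(strain = strain, replicate = replicate,
                        row.names = colnames(values))
  )
}

#' @rdname MultiOmicsExperiment-accessors
#' @export
setGeneric("rnaCounts", function(x, ...) standardGeneric("rnaCounts"))
#' @rdname MultiOmicsExperiment-accessors
#' @export
setGeneric("rpfCounts", function(x, ...) standardGeneric("rpfCounts"))
#' @rdname MultiOmicsExperiment-accessors
#' @export
setGeneric("msIntensities", function(x, ...) standardGeneric("msIntensities"))
#' @rdname MultiOmicsExperiment-accessors
#' @export
setGeneric("copyNumber", function(x, ...) standardGeneric("copyNumber"))
#' @rdname MultiOmicsExperiment-accessors
#' @export
setGeneric("geneData", function(x, ...) standardGeneric("geneData"))
#' @rdname MultiOmicsExperiment-accessors
#' @export
setGeneric("disruptedGenes", function(x, ...) standardGeneric("disruptedGenes"))
#' @rdname MultiOmicsExperiment-accessors
#' @export
setGeneric("ancestorStrain", function(x) standardGeneric("ancestorStrain"))
#' @rdname MultiOmicsExperiment-accessors
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))
#' @rdname MultiOmicsExperiment-accessors
#' @export
setGeneric("levelSamples", function(x, level) standardGeneric("levelSamples"))

#' Accessors for MultiOmicsExperiment
#'
#' \code{rnaCounts}, \code{rpfCounts} and \code{msIntensities} return the
#' assay matrices; \code{copyNumber} the genes x strains copy-number
#' matrix; \code{geneData} the annotation DataFrame; \code{disruptedGenes}
#' the logical disruption matrix; \code{ancestorStrain} and
#' \code{strainNames} the strain metadata; \code{levelSamples} the sample
#' table (strain, replicate) for one level.
#'
#' @param x A MultiOmicsExperiment.
#' @param level One of "RNA", "RPF", "MS".
#' @param ... unused.
#' @name MultiOmicsExperiment-accessors
NULL

#' @rdname MultiOmicsExperiment-accessors
setMethod("rnaCounts", "MultiOmicsExperiment", function(x, ...) assay(x@rna))
#' @rdname MultiOmicsExperiment-accessors
setMethod("rpfCounts", "MultiOmicsExperiment", function(x, ...) assay(x@rpf))
#' @rdname MultiOmicsExperiment-accessors
setMethod("msIntensities", "MultiOmicsExperiment", function(x, ...) assay(x@ms))
#' @rdname MultiOmicsExperiment-accessors
setMethod("copyNumber", "MultiOmicsExperiment", function(x, ...) x@copyNumber)
#' @rdname MultiOmicsExperiment-accessors
setMethod("geneData", "MultiOmicsExperiment", function(x, ...) x@geneData)
#' @rdname MultiOmicsExperiment-accessors
setMethod("disruptedGenes", "MultiOmicsExperiment", function(x, ...) x@disrupted)
#' @rdname MultiOmicsExperiment-accessors
setMethod("ancestorStrain", "MultiOmicsExperiment", function(x) x@ancestor)
#' @rdname MultiOmicsExperiment-accessors
setMethod("strainNames", "MultiOmicsExperiment",
          function(x) colnames(x@copyNumber))
#' @rdname MultiOmicsExperiment-accessors
setMethod("levelSamples", "MultiOmicsExperiment", function(x, level) {
  se <- levelSE(x, level)
  as.data.frame(colData(se))
})

# internal: pick the SummarizedExperiment for a level tag
levelSE <- function(x, level) {
  switch(toupper(level),
         RNA = x@rna, RPF = x@rpf, MS = x@ms,
         stop("unknown level: ", level))
}

#' Level assay matrix by tag
#' @param x MultiOmicsExperiment
#' @param level "RNA", "RPF" or "MS"
#' @return matrix genes x samples
#' @export
levelValues <- function(x, level) assay(levelSE(x, level))

#' Subset a MultiOmicsExperiment to a gene set
#' @param x MultiOmicsExperiment
#' @param genes character vector of gene ids (order respected)
#' @return MultiOmicsExperiment restricted to \code{genes}
#' @export
subsetGenes <- function(x, genes) {
  idx <- match(genes, x@geneData$gene_id)
  if (anyNA(idx)) stop("unknown gene ids in subsetGenes")
  new("MultiOmicsExperiment",
      rna = x@rna[idx, ], rpf = x@rpf[idx, ], ms = x@ms[idx, ],
      geneData = x@geneData[idx, , drop = FALSE],
      copyNumber = x@copyNumber[idx, , drop = FALSE],
      disrupted = x@disrupted[idx, , drop = FALSE],
      ancestor = x@ancestor)
}

setMethod("show", "MultiOmicsExperiment", function(object) {
  cat("MultiOmicsExperiment\n")
  cat(sprintf("  genes: %d\n", nrow(object@geneData)))
  for (lv in c("rna", "rpf", "ms")) {
    se <- slot(object, lv)
    cat(sprintf("  %s: %d samples (%s)\n", toupper(lv), ncol(se),
                paste(unique(colData(se)$strain), collapse = ", ")))
  }
  cat(sprintf("  strains: %s (ancestor: %s)\n",
              paste(colnames(object@copyNumber), collapse = ", "),
              object@ancestor))
  amp <- sum(apply(object@copyNumber, 1, max) >
             object@copyNumber[, object@ancestor])
  cat(sprintf("  CNV-amplified genes: %d\n", amp))
})

setMethod("show", "BoxCoxTransform", function(object) {
  cat(sprintf(
    "BoxCoxTransform(lambda = %.4f, offset = %g, range = [%.4g, %.4g], epsilon = %g)\n",
    object@lambda, object@offset, object@bcMin, object@bcMax, object@epsilon))
})
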