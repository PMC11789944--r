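#' @importFrom stats pnorm p.adjust fisher.test
NULL

#' Relative copy number of each gene in an evolved strain
#'
#' Evolved copy number divided by ancestor copy number, which handles
#' loci where the ancestor copy number is not 1.
#'
#' @param cn genes x strains copy-number matrix.
#' @param strain evolved strain name.
#' @param ancestor ancestor strain name.
#' @return numeric vector of relative copy numbers.
#' @export
relativeCopyNumber <- function(cn, strain, ancestor) {
  cn[, strain] / cn[, ancestor]
}

#' Expected counts under the copy-number null
#'
#' The null model of transcription efficiency: expected evolved
#' expression is the observed ancestor expression multiplied by the
#' relative copy number, replicate by replicate (ancestor replicate i
#' scales to expected replicate i, preserving replicate-level
#' dispersion), rounded to the nearest integer.
#'
#' @param ancestor_counts genes x replicates matrix of ancestor counts.
#' @param relative_cn per-gene relative copy number (>= 1).
#' @return matrix of expected counts, same shape as the input.
#' @export
expectedCounts <- function(ancestor_counts, relative_cn) {
  stopifnot(length(relative_cn) == nrow(ancestor_counts))
  round(ancestor_counts * relative_cn)
}

#' Negative-binomial test of observed versus expected counts
#'
#' Per-gene Wald test of the observed evolved counts against the
#' copy-number-scaled expected counts. Dispersion is estimated by method
#' of moments from the within-group variances; because the gene-wise
#' estimate has only ~2 degrees of freedom at 2 replicates, the test uses
#' the common (10\% trimmed mean) estimate across genes, floored at 1e-8
#' (the gene-wise values are still reported). A
#' pseudo-count of 1 replaces any zero cell. P-values are BH-corrected
#' across genes; \code{call = "lower"} is evidence of dosage attenuation.
#'
#' @param observed genes x replicates matrix of evolved counts.
#' @param expected genes x replicates matrix from
#'   \code{\link{expectedCounts}}.
#' @param dispersion optional fixed dispersion (scalar or per gene)
#'   overriding the method-of-moments estimate.
#' @param alpha BH-adjusted significance level.
#' @return data.frame: gene_id, observed/expected means, log2 ratio,
#'   dispersion, p, bh_adj_p, call.
#' @export
txnEfficiencyTest <- function(observed, expected, dispersion = NULL,
                              alpha = 0.05) {
  stopifnot(identical(dim(observed), dim(expected)),
            ncol(observed) >= 2)
  observed[observed == 0] <- 1
  expected[expected == 0] <- 1
  n1 <- ncol(observed)
  n2 <- ncol(expected)
  m1 <- rowMeans(observed)
  m2 <- rowMeans(expected)
  v1 <- apply(observed, 1, var)
  v2 <- apply(expected, 1, var)
  # method-of-moments: var = mu + alpha mu^2 within each group
  a1 <- (v1 - m1) / m1^2
  a2 <- (v2 - m2) / m2^2
  a_gene <- (a1 + a2) / 2
  if (is.null(dispersion)) {
    # with 2 replicates the gene-wise estimate has ~2 df, so the test
    # uses the common (trimmed-mean) estimate across genes
    dispersion <- pmax(rep(mean(a_gene, trim = 0.1, na.rm = TRUE),
                           nrow(observed)), 1e-8)
  } else {
    dispersion <- pmax(rep(dispersion, length.out = nrow(observed)), 1e-8)
  }
  se <- sqrt((1 / m1 + dispersion) / n1 + (1 / m2 + dispersion) / n2)
  z <- (log(m1) - log(m2)) / se
  p <- 2 * pnorm(-abs(z))
  padj <- p.adjust(p, "BH")
  call <- rep("none", nrow(observed))
  call[padj < alpha & z > 0] <- "higher"
  call[padj < alpha & z < 0] <- "lower"
  data.frame(
    gene_id = rownames(observed),
    observed_mean = m1, expected_mean = m2,
    log2_ratio_obs_vs_exp = log2(m1 / m2),
    dispersion = dispersion,
    p = p, bh_adj_p = pmax(padj, p), call = call,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Fisher's exact test of translation-efficiency ratios
#'
#' Compares the evolved RPF/RNA ratio to the ancestral ratio per gene.
#' Median TPMs per strain are rounded to the nearest integer to form the
#' 2x2 table [[RPF_evo, RNA_evo], [RPF_anc, RNA_anc]]; two-sided FET;
#' BH correction across tested genes. Genes with any zero cell after
#' rounding are excluded with a reason code.
#'
#' @param rpf_tpm,rna_tpm genes x samples TPM matrices.
#' @param samples_rpf,samples_rna sample tables (strain, replicate).
#' @param strain evolved strain.
#' @param ancestor ancestor strain.
#' @param alpha BH-adjusted significance level.
#' @return data.frame: gene_id, the four table cells, odds_ratio, p,
#'   bh_adj_p, call, excluded, reason.
#' @export
tlnEfficiencyFet <- function(rpf_tpm, rna_tpm, samples_rpf, samples_rna,
                             strain, ancestor, alpha = 0.05) {
  rpf_evo <- round(summarizeReplicates(rpf_tpm, samples_rpf, strain)$median)
  rpf_anc <- round(summarizeReplicates(rpf_tpm, samples_rpf, ancestor)$median)
  rna_evo <- round(summarizeReplicates(rna_tpm, samples_rna, strain)$median)
  rna_anc <- round(summarizeReplicates(rna_tpm, samples_rna, ancestor)$median)

  n <- nrow(rpf_tpm)
  excluded <- rpf_evo == 0 | rna_evo == 0 | rpf_anc == 0 | rna_anc == 0
  p <- rep(NA_real_, n)
  or <- rpf_evo * rna_anc / (rna_evo * rpf_anc)
  for (i in which(!excluded)) {
    tab <- matrix(c(rpf_evo[i], rna_evo[i], rpf_anc[i], rna_anc[i]),
                  2, 2, byrow = TRUE)
    p[i] <- fisher.test(tab)$p.value
  }
  padj <- rep(NA_real_, n)
  padj[!excluded] <- p.adjust(p[!excluded], "BH")
  call <- rep("none", n)
  call[!excluded & padj < alpha & or > 1] <- "higher"
  call[!excluded & padj < alpha & or < 1] <- "lower"
  data.frame(
    gene_id = rownames(rpf_tpm),
    rpf_evo = rpf_evo, rna_evo = rna_evo,
    rpf_anc = rpf_anc, rna_anc = rna_anc,
    odds_ratio = ifelse(excluded, NA_real_, or),
    p = p, bh_adj_p = padj, call = call,
    excluded = excluded,
    reason = ifelse(excluded, "zero_cell_after_rounding", ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
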