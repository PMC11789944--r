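#' Run the full multilevel efficiency pipeline
#'
#' Executes the stages in order: QC filtering, TPM normalization,
#' copy-number-corrected transcription-efficiency test (NB Wald, per
#' evolved strain), translation-efficiency FET, protein-expression
#' efficiency via TNNTg, uORF calling, Ssd1 motif scanning and the
#' enrichment/co-occurrence tests. Per-stage tables are written as TSV
#' under \code{out_dir} together with a JSON run summary echoing the
#' seed and thresholds. Given the same config (including seed) the
#' outputs are byte identical across runs.
#'
#' @param moe \linkS4class{MultiOmicsExperiment}.
#' @param tls named DNAStringSet of TL sequences (optional; uORF/motif
#'   stages are skipped when absent).
#' @param coverage named list of TL coverage matrices (needed for uORFs).
#' @param validated_uorfs data.frame (gene_id, tl_offset, length) of
#'   validated uORFs used to curate the training set.
#' @param config \code{\link{pipelineConfig}}.
#' @param out_dir output directory.
#' @return invisibly, a list with the per-stage results and the summary.
#' @export
runPipeline <- function(moe, tls = NULL, coverage = NULL,
                        validated_uorfs = NULL,
                        config = pipelineConfig(), out_dir) {
  if (!(ancestorStrain(moe) %in% strainNames(moe))) {
    stop("ancestor strain missing from dataset")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  anc <- ancestorStrain(moe)
  evolved <- setdiff(strainNames(moe), anc)

  qc <- qcFilter(moe, config)
  sub <- subsetGenes(moe, qc$retained)
  writeResultTable(qc$reasons, file.path(out_dir, "qc_removed.tsv"))

  cds_len <- geneData(sub)$cds_length
  rna_tpm <- tpm(rnaCounts(sub), cds_len)
  rpf_tpm <- tpm(rpfCounts(sub), cds_len)
  smp_rna <- levelSamples(sub, "RNA")
  smp_rpf <- levelSamples(sub, "RPF")

  strainCols <- function(m, smp, s) m[, smp$strain == s, drop = FALSE]
  cn <- copyNumber(sub)

  txn <- list(); tln <- list(); prot <- list()
  for (s in evolved) {
    keep <- !(geneData(sub)$gene_id %in% qc$per_strain_excluded[[s]])
    strain_sub <- subsetGenes(sub, geneData(sub)$gene_id[keep])

    obs <- strainCols(rnaCounts(strain_sub), levelSamples(strain_sub, "RNA"), s)
    anc_counts <- strainCols(rnaCounts(strain_sub),
                             levelSamples(strain_sub, "RNA"), anc)
    if (config$library_size_normalize) {
      sizes <- colSums(rnaCounts(strain_sub))
      fac <- mean(sizes) / sizes
      obs <- round(sweep(obs, 2, fac[colnames(obs)], "*"))
      anc_counts <- round(sweep(anc_counts, 2, fac[colnames(anc_counts)], "*"))
    }
    rcn <- relativeCopyNumber(copyNumber(strain_sub), s, anc)
    expd <- expectedCounts(anc_counts, rcn)
    tx <- txnEfficiencyTest(obs, expd, alpha = config$alpha)
    tx$strain <- s
    txn[[s]] <- tx

    te <- tlnEfficiencyFet(
      tpm(rpfCounts(strain_sub), geneData(strain_sub)$cds_length),
      tpm(rnaCounts(strain_sub), geneData(strain_sub)$cds_length),
      levelSamples(strain_sub, "RPF"), levelSamples(strain_sub, "RNA"),
      s, anc, alpha = config$alpha)
    te$strain <- s
    tln[[s]] <- te

    pe <- efficiencyOutliers(strain_sub, s, "MS/RPF", config)
    prot[[s]] <- pe
  }
  txn <- do.call(rbind, txn)
  tln <- do.call(rbind, tln)
  prot <- do.call(rbind, prot)
  writeResultTable(txn, file.path(out_dir, "transcription_efficiency.tsv"))
  writeResultTable(tln, file.path(out_dir, "translation_efficiency.tsv"))
  writeResultTable(prot, file.path(out_dir, "protein_efficiency.tsv"))

  uorf <- NULL
  motif_hits <- NULL
  enrich <- list()
  if (!is.null(tls)) {
    tl_genes <- intersect(names(tls), qc$retained)
    motif_hits <- do.call(rbind, lapply(tl_genes, function(g) {
      h <- scanMotif(tls[[g]], config$motif)
      if (nrow(h)) cbind(gene_id = g, h, stringsAsFactors = FALSE) else NULL
    }))
    tl_len <- nchar(as.character(tls[tl_genes]))
    names(tl_len) <- tl_genes
    total_len <- sum(tl_len)
    hit_counts <- table(factor(motif_hits$gene_id, levels = tl_genes))
    total_hits <- sum(hit_counts)
    motif_enriched <- vapply(tl_genes, function(g) {
      perGeneFet(as.integer(hit_counts[[g]]), tl_len[[g]],
                 total_hits, total_len, config$alpha)$enriched
    }, NA)
    writeResultTable(
      data.frame(gene_id = tl_genes, hits = as.integer(hit_counts),
                 tl_length = as.integer(tl_len),
                 enriched = motif_enriched),
      file.path(out_dir, "motif_enrichment.tsv"))
    if (!is.null(motif_hits)) {
      writeResultTable(motif_hits, file.path(out_dir, "motif_hits.tsv"))
    }

    if (!is.null(coverage) && !is.null(validated_uorfs)) {
      uorf <- callUorfs(tls[tl_genes], coverage[tl_genes],
                        validated_uorfs, config)
      writeResultTable(uorf$candidates,
                       file.path(out_dir, "uorf_candidates.tsv"))

      # gene-set enrichments mirroring the study's overlap tests
      uorf_genes <- unique(uorf$candidates$gene_id[
        uorf$candidates$high_confidence])
      te_genes <- unique(tln$gene_id[tln$call != "none"])
      ms_genes <- names(motif_enriched)[motif_enriched]
      N <- length(qc$retained)
      ov <- function(a, b) {
        if (!length(a) || !length(b)) return(NULL)
        hypergeomOverlap(length(intersect(a, b)), length(a), length(b), N)
      }
      enrich$uorf_x_te <- ov(uorf_genes, te_genes)
      enrich$uorf_x_motif <- ov(uorf_genes, ms_genes)
      enrich$motif_x_te <- ov(ms_genes, te_genes)

      upos <- split(uorf$candidates$tl_offset[uorf$candidates$high_confidence],
                    uorf$candidates$gene_id[uorf$candidates$high_confidence])
      mpos <- split(motif_hits$tl_position, motif_hits$gene_id)
      common <- intersect(names(upos), names(mpos))
      if (length(common)) {
        enrich$reldist <- reldistCooccurrence(
          upos[common], mpos[common],
          as.list(tl_len[common]), seed = config$rng_seed)
      }
    }
  }

  summary <- list(
    config = unclass(config),
    n_genes_input = nrow(geneData(moe)),
    n_genes_retained = length(qc$retained),
    per_strain_excluded = lapply(qc$per_strain_excluded, length),
    txn_significant = sum(txn$call != "none"),
    tln_significant = sum(tln$call != "none", na.rm = TRUE),
    prot_significant = sum(prot$call != "none"),
    n_high_confidence_uorf_genes = if (!is.null(uorf)) {
      length(unique(uorf$candidates$gene_id[uorf$candidates$high_confidence]))
    } else NA,
    n_motif_hits = if (!is.null(motif_hits)) nrow(motif_hits) else NA,
    enrichment = lapply(enrich, function(e) e[setdiff(names(e), "table")])
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(qc = qc, txn = txn, tln = tln, prot = prot,
                 uorf = uorf, motif_hits = motif_hits,
                 enrichment = enrich, summary = summary))
}
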