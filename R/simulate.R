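#' @importFrom stats rnbinom rpois rnorm runif median quantile rbinom
NULL

#' Simulation parameters for the synthetic multi-omic study
#'
#' Defines the study design the generator emulates: one ancestor plus
#' four evolved strains, each evolved strain carrying a contiguous block
#' of CNV-amplified genes (copy number 2-4) that share a 17-gene common
#' core; negative-binomial RNA/RPF counts with 2 replicates per strain;
#' log-normal MS intensities with 5 replicates on a scale several orders
#' of magnitude above the count scale; transcript leaders carrying
#' planted Ssd1 motifs and translated uORFs.
#'
#' @param n_genes number of genes.
#' @param n_cnv_genes CNV block size per evolved strain (>= core_size).
#' @param core_size number of CNV genes common to all evolved strains.
#' @param cnv_cn_values candidate copy numbers for a CNV block.
#' @param rna_depth,rpf_depth mean counts per gene for RNA and RPF.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param ms_scale multiplicative factor from RPF means to MS intensity
#'   means (keeps MS 2-4 orders of magnitude above counts).
#' @param ms_lognormal_sigma sd of log-normal MS noise (log scale).
#' @param ms_missing_fraction fraction of genes not detected by MS.
#' @param fraction_affected fraction of genes planted with an effect at
#'   each level (named: txn, tln, prot).
#' @param txn_attenuation attenuation factor for affected genes (RNA mean
#'   is base * CN * attenuation; 1 = fully proportional to CN).
#' @param tln_effect,prot_effect multiplicative effect sizes for affected
#'   genes; each affected gene is up- or down-shifted with equal
#'   probability (effect or 1/effect).
#' @param transposon_fraction fraction of genes flagged transposon
#'   associated.
#' @param n_rna_reps,n_rpf_reps,n_ms_reps replicates per strain.
#' @param tl_length_meanlog,tl_length_sdlog log-normal TL length
#'   parameters (clipped to [tl_min_length, tl_max_length]).
#' @param tl_min_length,tl_max_length TL length bounds (nt).
#' @param base_comp nucleotide probabilities (A, C, G, T) of background
#'   TL sequence.
#' @param uorf_fraction fraction of TLs with one planted translated uORF.
#' @param motif_fraction fraction of TLs with planted CNYUCNYU motifs.
#' @param motifs_per_tl planted motif copies per motif-carrying TL.
#' @param uorf_body_rate,uorf_offframe_rate,background_rate Poisson
#'   coverage rates (per nt per replicate) for in-frame uORF positions,
#'   out-of-frame uORF positions, and non-uORF background.
#' @param start_peak_factor coverage multiplier over the first two codons
#'   of a planted uORF.
#' @param rng_seed integer seed; every generator is a pure function of
#'   (params, seed).
#' @return list of class \code{cnveff_simparams}.
#' @export
simulationParams <- function(n_genes = 4000,
                             n_cnv_genes = 25,
                             core_size = 17,
                             cnv_cn_values = c(2L, 3L, 4L),
                             rna_depth = 1000,
                             rpf_depth = 500,
                             nb_dispersion = 0.05,
                             ms_scale = 1000,
                             ms_lognormal_sigma = 0.1,
                             ms_missing_fraction = 0.01,
                             fraction_affected = c(txn = 0.10, tln = 0.10,
                                                   prot = 0.10),
                             txn_attenuation = 0.5,
                             tln_effect = 2,
                             prot_effect = 2,
                             transposon_fraction = 0.02,
                             n_rna_reps = 2L, n_rpf_reps = 2L, n_ms_reps = 5L,
                             tl_length_meanlog = log(150),
                             tl_length_sdlog = 0.4,
                             tl_min_length = 40L, tl_max_length = 500L,
                             base_comp = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                             uorf_fraction = 0.10,
                             motif_fraction = 0.10,
                             motifs_per_tl = 1L,
                             uorf_body_rate = 8,
                             uorf_offframe_rate = 1,
                             background_rate = 0.2,
                             start_peak_factor = 2,
                             rng_seed = 1L) {
  stopifnot(
    n_genes >= 100, n_cnv_genes >= core_size,
    all(cnv_cn_values >= 2), nb_dispersion >= 0,
    all(fraction_affected >= 0 & fraction_affected <= 1),
    txn_attenuation > 0, txn_attenuation <= 1,
    tln_effect > 0, prot_effect > 0,
    abs(sum(base_comp) - 1) < 1e-8
  )
  structure(as.list(environment()), class = "cnveff_simparams")
}

# strains of the emulated design: 1 ancestor + 4 evolved lineages
simStrains <- function() c("ancestor", paste0("evolved", 1:4))

# sample() treats a length-1 numeric as 1:x; guard against that
sampleOne <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Generate the ground-truth table
#'
#' Draws per-gene copy numbers (contiguous CNV blocks per evolved strain
#' around a shared common core), planted expression effects at each
#' level, and planted TL features (uORF coordinates, motif positions).
#' Effects apply in every evolved strain relative to the ancestor.
#'
#' @param params \code{\link{simulationParams}}.
#' @return data.frame with one row per gene: copy number per strain
#'   (\code{cn_<strain>}), \code{disrupted_<strain>} flags,
#'   \code{txn_attenuation}, \code{tln_effect}, \code{prot_effect},
#'   \code{transposon_associated}, \code{tl_length}, \code{has_uorf},
#'   \code{uorf_start}, \code{uorf_length}, \code{has_motif},
#'   \code{motif_positions} (comma-separated 0-based TL offsets).
#' @export
simulateTruth <- function(params) {
  set.seed(params$rng_seed)
  n <- params$n_genes
  strains <- simStrains()
  gene_id <- sprintf("gene%04d", seq_len(n))

  cn <- matrix(1L, n, length(strains), dimnames = list(gene_id, strains))
  dis <- matrix(FALSE, n, length(strains), dimnames = list(gene_id, strains))
  # common core occupies a fixed window; each evolved strain extends it
  core_start <- max(2L, floor(n * 0.25))
  core <- core_start:(core_start + params$core_size - 1L)
  extra <- params$n_cnv_genes - params$core_size
  for (k in 1:4) {
    s <- strains[k + 1L]
    pre <- sample.int(extra + 1L, 1L) - 1L
    post <- extra - pre
    block <- (min(core) - pre):(max(core) + post)
    block <- block[block >= 1L & block <= n]
    cn[block, s] <- as.integer(sampleOne(params$cnv_cn_values))
    # breakpoint genes flanking the block are disrupted in that strain
    for (b in c(min(block) - 1L, max(block) + 1L)) {
      if (b >= 1L && b <= n) dis[b, s] <- TRUE
    }
  }

  pick <- function(frac) {
    sample.int(n, size = round(frac * n)) # affected gene indices
  }
  txn_att <- rep(1, n)
  txn_att[pick(params$fraction_affected[["txn"]])] <- params$txn_attenuation
  sgn_effect <- function(frac, size) {
    e <- rep(1, n)
    idx <- pick(frac)
    up <- rbinom(length(idx), 1L, 0.5) == 1L
    e[idx] <- ifelse(up, size, 1 / size)
    e
  }
  tln <- sgn_effect(params$fraction_affected[["tln"]], params$tln_effect)
  prot <- sgn_effect(params$fraction_affected[["prot"]], params$prot_effect)

  transposon <- rep(FALSE, n)
  transposon[pick(params$transposon_fraction)] <- TRUE

  tl_len <- pmin(pmax(round(exp(rnorm(n, params$tl_length_meanlog,
                                      params$tl_length_sdlog))),
                      params$tl_min_length), params$tl_max_length)

  has_uorf <- rep(FALSE, n)
  has_uorf[pick(params$uorf_fraction)] <- TRUE
  uorf_start <- rep(NA_integer_, n)
  uorf_len <- rep(NA_integer_, n)
  for (i in which(has_uorf)) {
    # length multiple of 3 within [12, min(90, tl - 6)]
    maxlen <- min(90L, tl_len[i] - 6L)
    len <- 3L * sampleOne(4:(maxlen %/% 3L))
    uorf_len[i] <- len
    uorf_start[i] <- sample.int(tl_len[i] - len + 1L, 1L) - 1L
  }

  has_motif <- rep(FALSE, n)
  has_motif[pick(params$motif_fraction)] <- TRUE
  motif_pos <- rep(NA_character_, n)
  for (i in which(has_motif)) {
    # plant motifs clear of the uORF and of each other
    occupied <- if (has_uorf[i]) {
      seq(uorf_start[i], uorf_start[i] + uorf_len[i] - 1L)
    } else integer()
    pos <- integer()
    for (m in seq_len(params$motifs_per_tl)) {
      ok <- setdiff(seq(0L, tl_len[i] - 8L), unique(unlist(
        lapply(c(pos, occupied), function(p) (p - 7L):(p + 7L)))))
      if (!length(ok)) break
      pos <- c(pos, sampleOne(ok))
    }
    if (length(pos)) {
      motif_pos[i] <- paste(sort(pos), collapse = ",")
    } else {
      has_motif[i] <- FALSE
    }
  }

  truth <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  for (s in strains) truth[[paste0("cn_", s)]] <- cn[, s]
  for (s in strains) truth[[paste0("disrupted_", s)]] <- dis[, s]
  truth$txn_attenuation <- txn_att
  truth$tln_effect <- tln
  truth$prot_effect <- prot
  truth$transposon_associated <- transposon
  truth$tl_length <- tl_len
  truth$has_uorf <- has_uorf
  truth$uorf_start <- uorf_start
  truth$uorf_length <- uorf_len
  truth$has_motif <- has_motif
  truth$motif_positions <- motif_pos
  truth
}

# NB draw with Poisson limit at zero dispersion
rcounts <- function(n, mu, dispersion) {
  if (dispersion < 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

truthCnMatrix <- function(truth) {
  strains <- simStrains()
  cn <- as.matrix(truth[, paste0("cn_", strains)])
  dimnames(cn) <- list(truth$gene_id, strains)
  storage.mode(cn) <- "integer"
  cn
}

truthDisruptedMatrix <- function(truth) {
  strains <- simStrains()
  d <- as.matrix(truth[, paste0("disrupted_", strains)])
  dimnames(d) <- list(truth$gene_id, strains)
  d
}

# deterministic per-gene per-strain expectation at each level
simMeans <- function(params, truth) {
  set.seed(params$rng_seed + 1L)
  n <- params$n_genes
  strains <- simStrains()
  base_rna <- exp(rnorm(n, log(params$rna_depth), 0.7))
  base_te <- exp(rnorm(n, log(params$rpf_depth / params$rna_depth), 0.3))
  cn <- truthCnMatrix(truth)
  rna_mu <- matrix(0, n, length(strains), dimnames = dimnames(cn))
  rpf_mu <- rna_mu
  ms_mu <- rna_mu
  for (s in strains) {
    evolved <- s != "ancestor"
    att <- if (evolved) truth$txn_attenuation else 1
    tln <- if (evolved) truth$tln_effect else 1
    prot <- if (evolved) truth$prot_effect else 1
    rna_mu[, s] <- base_rna * cn[, s] * att
    rpf_mu[, s] <- rna_mu[, s] * base_te * tln
    ms_mu[, s] <- params$ms_scale * rpf_mu[, s] * prot
  }
  list(rna = rna_mu, rpf = rpf_mu, ms = ms_mu)
}

#' Simulate RNA and RPF count matrices
#'
#' Gene g in strain s has RNA mean base_g x CN(g,s) x attenuation and RPF
#' mean RNA mean x base TE x translation effect; counts are drawn
#' negative-binomial with the configured dispersion, 2 replicates per
#' strain by default.
#'
#' @param params \code{\link{simulationParams}}.
#' @param truth output of \code{\link{simulateTruth}}.
#' @return list of SummarizedExperiments \code{rna} and \code{rpf}.
#' @export
simulateCounts <- function(params, truth) {
  mu <- simMeans(params, truth)
  set.seed(params$rng_seed + 2L)
  draw <- function(mumat, nreps) {
    strains <- colnames(mumat)
    cols <- unlist(lapply(strains, function(s) paste0(s, ":", seq_len(nreps))))
    m <- matrix(0L, nrow(mumat), length(cols),
                dimnames = list(rownames(mumat), cols))
    for (s in strains) {
      for (r in seq_len(nreps)) {
        m[, paste0(s, ":", r)] <- rcounts(nrow(mumat), mumat[, s],
                                          params$nb_dispersion)
      }
    }
    storage.mode(m) <- "integer"
    m
  }
  list(rna = makeLevelSE(draw(mu$rna, params$n_rna_reps)),
       rpf = makeLevelSE(draw(mu$rpf, params$n_rpf_reps)))
}

#' Simulate the MS intensity matrix
#'
#' MS intensity mean is \code{ms_scale} x RPF mean x protein-efficiency
#' effect, placed 2-4 orders of magnitude above the count scale so the
#' scale-mismatch the transformed near-neighbor test addresses is
#' exercised; log-normal noise; 5 replicates per strain. A configurable
#' fraction of genes is "not detected" (NA in every sample).
#'
#' @param params \code{\link{simulationParams}}.
#' @param truth ground-truth table.
#' @return SummarizedExperiment of intensities.
#' @export
simulateMs <- function(params, truth) {
  mu <- simMeans(params, truth)$ms
  set.seed(params$rng_seed + 3L)
  strains <- colnames(mu)
  cols <- unlist(lapply(strains, function(s)
    paste0(s, ":", seq_len(params$n_ms_reps))))
  m <- matrix(0, nrow(mu), length(cols), dimnames = list(rownames(mu), cols))
  for (s in strains) {
    for (r in seq_len(params$n_ms_reps)) {
      noise <- if (params$ms_lognormal_sigma > 0) {
        exp(rnorm(nrow(mu), 0, params$ms_lognormal_sigma))
      } else 1
      m[, paste0(s, ":", r)] <- mu[, s] * noise
    }
  }
  n_miss <- round(params$ms_missing_fraction * nrow(mu))
  if (n_miss > 0) m[sample.int(nrow(mu), n_miss), ] <- NA_real_
  makeLevelSE(m)
}

# concrete instance of the degenerate Ssd1 motif (DNA alphabet)
sampleMotifInstance <- function() {
  paste0(c("C", sample(c("A", "C", "G", "T"), 1), sample(c("C", "T"), 1), "T",
           "C", sample(c("A", "C", "G", "T"), 1), sample(c("C", "T"), 1), "T"),
         collapse = "")
}

# random codons avoiding stop codons
sampleBodyCodons <- function(n_codons, base_comp) {
  stops <- c("TAA", "TAG", "TGA")
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- paste0(sample(names(base_comp), 3, TRUE, base_comp), collapse = "")
      if (!(cod %in% stops)) break
    }
    out[i] <- cod
  }
  out
}

#' Simulate TL sequences and footprint coverage
#'
#' Background sequence is i.i.d. with the configured base composition.
#' Planted uORFs get an AUG start, stop-free body codons and an in-frame
#' stop, plus elevated 3-periodic footprint coverage with a start-codon
#' peak; planted CNYUCNYU motif instances are written at the truth
#' positions. Non-uORF positions get low uniform Poisson noise coverage.
#'
#' @param params \code{\link{simulationParams}}.
#' @param truth ground-truth table.
#' @return list: \code{tls} (DNAStringSet named by gene) and
#'   \code{coverage} (per gene a TL-length x n_rpf_reps matrix).
#' @export
simulateTls <- function(params, truth) {
  set.seed(params$rng_seed + 4L)
  n <- nrow(truth)
  alphabet <- names(params$base_comp)
  seqs <- character(n)
  coverage <- vector("list", n)
  for (i in seq_len(n)) {
    len <- truth$tl_length[i]
    s <- sample(alphabet, len, TRUE, params$base_comp)
    if (isTRUE(truth$has_uorf[i])) {
      st <- truth$uorf_start[i]
      ul <- truth$uorf_length[i]
      body <- sampleBodyCodons(ul / 3L - 2L, params$base_comp)
      uorf_seq <- strsplit(paste0("ATG", paste(body, collapse = ""), "TAA"),
                           "")[[1]]
      s[(st + 1L):(st + ul)] <- uorf_seq
      # no spurious upstream in-frame AUG creating a longer ORF is needed;
      # enumeration reports all candidates and truth matching is by position
    }
    if (isTRUE(truth$has_motif[i])) {
      for (p in as.integer(strsplit(truth$motif_positions[i], ",")[[1]])) {
        s[(p + 1L):(p + 8L)] <- strsplit(sampleMotifInstance(), "")[[1]]
      }
    }
    seqs[i] <- paste(s, collapse = "")

    cov <- matrix(rpois(len * params$n_rpf_reps, params$background_rate),
                  nrow = len)
    if (isTRUE(truth$has_uorf[i])) {
      st <- truth$uorf_start[i]
      ul <- truth$uorf_length[i]
      pos <- st:(st + ul - 1L)
      frame0 <- pos[(pos - st) %% 3L == 0L]
      other <- setdiff(pos, frame0)
      for (r in seq_len(params$n_rpf_reps)) {
        rate0 <- rep(params$uorf_body_rate, length(frame0))
        rate0[1:2] <- rate0[1:2] * params$start_peak_factor
        cov[frame0 + 1L, r] <- rpois(length(frame0), rate0)
        cov[other + 1L, r] <- rpois(length(other), params$uorf_offframe_rate)
      }
    }
    coverage[[i]] <- cov
  }
  tls <- DNAStringSet(seqs)
  names(tls) <- truth$gene_id
  names(coverage) <- truth$gene_id
  list(tls = tls, coverage = coverage)
}

#' Simulate a complete multi-omic experiment with ground truth
#'
#' Runs every generator under one seed and assembles the
#' \linkS4class{MultiOmicsExperiment} plus gene annotation, TL sequences,
#' footprint coverage and the truth table.
#'
#' @param params \code{\link{simulationParams}}.
#' @return list with elements \code{moe}, \code{truth}, \code{tls},
#'   \code{coverage}, \code{params}.
#' @export
simulateExperiment <- function(params = simulationParams()) {
  truth <- simulateTruth(params)
  counts <- simulateCounts(params, truth)
  ms <- simulateMs(params, truth)
  tl <- simulateTls(params, truth)

  n <- nrow(truth)
  # simple gene geometry: genes tiled along one chromosome, TL upstream
  cds_len <- rep(900L, n)
  gaps <- 600L
  starts <- cumsum(c(1000L, rep(cds_len[1] + gaps, n - 1L)))
  geneData <- DataFrame(
    gene_id = truth$gene_id,
    chrom = "chrS",
    start = starts, end = starts + cds_len,
    strand = "+",
    cds_length = cds_len,
    tl_start = starts - truth$tl_length,
    tl_end = starts,
    transposon_associated = truth$transposon_associated
  )
  moe <- MultiOmicsExperiment(
    rna = counts$rna, rpf = counts$rpf, ms = ms,
    geneData = geneData,
    copyNumber = truthCnMatrix(truth),
    disrupted = truthDisruptedMatrix(truth),
    ancestor = "ancestor"
  )
  list(moe = moe, truth = truth, tls = tl$tls, coverage = tl$coverage,
       params = params)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Writes the count/intensity matrices and copy-number table as TSV, TL
#' sequences as FASTA, coverage as sparse TSV, gene models as GFF3 and
#' the truth table as truth.tsv — the same formats the readers consume.
#'
#' @param sim output of \code{\link{simulateExperiment}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    rna = file.path(dir, "rna_counts.tsv"),
    rpf = file.path(dir, "rpf_counts.tsv"),
    ms = file.path(dir, "ms_intensities.tsv"),
    cn = file.path(dir, "copy_number.tsv"),
    tls = file.path(dir, "tl_sequences.fasta"),
    coverage = file.path(dir, "tl_coverage.tsv"),
    gff = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.tsv")
  )
  writeExpression(sim$moe@rna, paths["rna"])
  writeExpression(sim$moe@rpf, paths["rpf"])
  writeExpression(sim$moe@ms, paths["ms"])

  cn <- copyNumber(sim$moe)
  dis <- disruptedGenes(sim$moe)
  cn_df <- do.call(rbind, lapply(colnames(cn), function(s) {
    data.frame(gene_id = rownames(cn), strain = s, copy_number = cn[, s],
               disrupted = dis[, s])
  }))
  writeResultTable(cn_df, paths["cn"])

  writeXStringSet(sim$tls, paths["tls"])
  writeCoverage(sim$coverage, paths["coverage"])

  gd <- geneData(sim$moe)
  gr <- GRanges(gd$chrom,
                IRanges(gd$start + 1L, gd$end), strand = gd$strand)
  S4Vectors::mcols(gr) <- DataFrame(
    type = "gene", ID = gd$gene_id, cds_length = gd$cds_length,
    tl_start = gd$tl_start + 1L, tl_end = gd$tl_end,
    transposon_associated = gd$transposon_associated)
  rtracklayer::export(gr, paths["gff"], format = "gff3")

  writeResultTable(sim$truth, paths["truth"])
  invisible(paths)
}
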