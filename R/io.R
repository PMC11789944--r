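#' @importFrom utils read.delim write.table
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
NULL

# GFF3 is 1-based closed; internal coordinates are 0-based half-open.
gffToInternal <- function(start, end) cbind(start = start - 1L, end = end)
internalToGff <- function(start, end) cbind(start = start + 1L, end = end)

#' Read gene annotations and per-strain copy numbers
#'
#' Reads gene models from a GFF3 file (features of type \code{gene};
#' attributes \code{ID} as gene id, optional \code{cds_length},
#' \code{tl_start}/\code{tl_end} in 1-based genome coordinates, optional
#' \code{transposon_associated}) and joins a copy-number table with
#' columns \code{gene_id}, \code{strain}, \code{copy_number} and optional
#' \code{disrupted}. Genes absent from the copy-number table are assigned
#' copy number 1 in every strain. Coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param gff3_path path to a GFF3 file.
#' @param cn_table_path path to a TSV copy-number table.
#' @param strains optional character vector fixing the strain set (and
#'   column order); defaults to the strains present in the table.
#' @return list with elements \code{geneData} (DataFrame),
#'   \code{copyNumber} (integer matrix) and \code{disrupted} (logical
#'   matrix).
#' @export
readAnnotations <- function(gff3_path, cn_table_path, strains = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (anyDuplicated(ids)) stop("duplicate gene_id in GFF3")
  co <- gffToInternal(start(gr), end(gr))
  md <- S4Vectors::mcols(gr)
  pick_num <- function(col, default) {
    if (col %in% colnames(md)) as.numeric(md[[col]]) else rep(default, length(gr))
  }
  cds_length <- pick_num("cds_length", NA_real_)
  if (all(is.na(cds_length))) cds_length <- co[, "end"] - co[, "start"]
  if (any(cds_length <= 0, na.rm = TRUE)) stop("cds_length must be > 0")
  tl_start <- pick_num("tl_start", NA_real_)
  tl_end <- pick_num("tl_end", NA_real_)
  tl_start <- ifelse(is.na(tl_start), NA_integer_, as.integer(tl_start) - 1L)
  tl_end <- as.integer(tl_end)
  transposon <- if ("transposon_associated" %in% colnames(md)) {
    as.logical(md$transposon_associated)
  } else rep(FALSE, length(gr))
  transposon[is.na(transposon)] <- FALSE

  geneData <- DataFrame(
    gene_id = ids,
    chrom = as.character(seqnames(gr)),
    start = co[, "start"], end = co[, "end"],
    strand = as.character(strand(gr)),
    cds_length = as.integer(cds_length),
    tl_start = tl_start, tl_end = tl_end,
    transposon_associated = transposon
  )

  cn <- read.delim(cn_table_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "strain", "copy_number")
  if (!all(need %in% colnames(cn))) {
    stop("copy-number table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(cn$copy_number <= 0)) stop("copy number must be positive")
  if (anyDuplicated(cn[, c("gene_id", "strain")])) {
    stop("duplicate (gene, strain) rows in copy-number table")
  }
  if (is.null(strains)) strains <- sort(unique(cn$strain))
  cnm <- matrix(1L, nrow = length(ids), ncol = length(strains),
                dimnames = list(ids, strains))
  dis <- matrix(FALSE, nrow = length(ids), ncol = length(strains),
                dimnames = list(ids, strains))
  keep <- cn$gene_id %in% ids & cn$strain %in% strains
  cn <- cn[keep, , drop = FALSE]
  cnm[cbind(cn$gene_id, cn$strain)] <- as.integer(cn$copy_number)
  if ("disrupted" %in% colnames(cn)) {
    dis[cbind(cn$gene_id, cn$strain)] <- as.logical(cn$disrupted)
  }
  list(geneData = geneData, copyNumber = cnm, disrupted = dis)
}

#' Read an expression matrix from TSV
#'
#' Rows are keyed by \code{gene_id}; remaining columns are samples named
#' \code{strain:replicate}. RNA/RPF values must be non-negative integers.
#' For MS, empty cells or \code{NA} mean "not detected" and are kept as
#' \code{NA}, distinct from zero.
#'
#' @param tsv_path path to the TSV file.
#' @param level "RNA", "RPF" or "MS".
#' @param gene_ids optional gene order to align rows to; genes missing
#'   from the file are filled with NA rows.
#' @return A SummarizedExperiment (see \code{\link{makeLevelSE}}).
#' @export
readExpression <- function(tsv_path, level, gene_ids = NULL) {
  level <- toupper(level)
  df <- read.delim(tsv_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  if (any(m < 0, na.rm = TRUE)) stop("negative expression value")
  if (level %in% c("RNA", "RPF")) {
    if (anyNA(m)) stop(level, " counts cannot be missing")
    if (any(m != round(m))) stop(level, " counts must be integers")
  }
  if (!is.null(gene_ids)) {
    out <- matrix(NA_real_, length(gene_ids), ncol(m),
                  dimnames = list(gene_ids, colnames(m)))
    hit <- intersect(gene_ids, rownames(m))
    out[hit, ] <- m[hit, ]
    m <- out
  }
  makeLevelSE(m)
}

#' Write an expression matrix to TSV
#'
#' Inverse of \code{\link{readExpression}}: NA cells are written empty
#' (MS "not detected"), so a write/read round trip reproduces the matrix.
#'
#' @param se SummarizedExperiment or plain matrix.
#' @param tsv_path output path.
#' @export
writeExpression <- function(se, tsv_path) {
  m <- if (is(se, "SummarizedExperiment")) assay(se) else se
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' Read transcript-leader sequences from FASTA
#'
#' @param fasta_path FASTA of TL sequences, names = gene ids.
#' @return DNAStringSet (U normalized to T).
#' @export
readTlSequences <- function(fasta_path) {
  readDNAStringSet(fasta_path)
}

#' Read per-nucleotide TL footprint coverage
#'
#' Accepts a TSV with columns \code{gene_id}, \code{pos} (0-based TL
#' offset) and one column per replicate, dense or sparse (absent
#' positions are zero).
#'
#' @param path coverage TSV.
#' @param tl_lengths named integer vector of TL lengths.
#' @return named list: per gene a matrix length x replicates.
#' @export
readCoverage <- function(path, tl_lengths) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  repcols <- setdiff(colnames(df), c("gene_id", "pos"))
  out <- lapply(names(tl_lengths), function(g) {
    m <- matrix(0, nrow = tl_lengths[[g]], ncol = length(repcols),
                dimnames = list(NULL, repcols))
    sub <- df[df$gene_id == g, , drop = FALSE]
    if (nrow(sub)) m[sub$pos + 1L, ] <- as.matrix(sub[, repcols])
    m
  })
  names(out) <- names(tl_lengths)
  out
}

#' Write per-nucleotide TL coverage tracks
#' @param coverage named list of length x replicate matrices.
#' @param path output TSV (sparse; zero rows omitted).
#' @export
writeCoverage <- function(coverage, path) {
  rows <- lapply(names(coverage), function(g) {
    m <- coverage[[g]]
    nz <- which(rowSums(m) > 0)
    if (!length(nz)) return(NULL)
    data.frame(gene_id = g, pos = nz - 1L, m[nz, , drop = FALSE],
               check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a result table to TSV
#' @param df data.frame of results.
#' @param path output path.
#' @export
writeResultTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

#' Write intervals as BED6
#'
#' @param df data.frame with columns chrom, start (0-based), end, name,
#'   score, strand.
#' @param path output path.
#' @export
writeBed6 <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand") %in%
                colnames(df)))
  write.table(df[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}
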