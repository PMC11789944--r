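#' @importFrom stats phyper ks.test punif
#' @importFrom Biostrings matchPattern reverseComplement DNAString
NULL

#' Scan a transcript leader for a degenerate motif
#'
#' Finds all (overlapping) perfect matches to the degenerate Ssd1 motif
#' on the forward sequence and its reverse complement, reporting
#' positions on forward coordinates with a strand tag. IUPAC degeneracy:
#' N = any base, Y = pyrimidine (C or U/T). The default motif CNYUCNYU is
#' matched as CNYTCNYT on the DNA alphabet.
#'
#' @param tl_seq sequence (character, RNA or DNA alphabet).
#' @param motif degenerate motif (default "CNYUCNYU").
#' @return data.frame: tl_position (0-based), strand, matched_seq
#'   (forward-strand 8-mer).
#' @export
scanMotif <- function(tl_seq, motif = "CNYUCNYU") {
  s <- normalizeSeq(tl_seq)
  pat <- DNAString(normalizeSeq(motif))
  empty <- data.frame(tl_position = integer(), strand = character(),
                      matched_seq = character(), stringsAsFactors = FALSE)
  if (nchar(s) < length(pat)) return(empty)
  subj <- DNAString(s)
  fwd <- matchPattern(pat, subj, fixed = FALSE)
  rev_ <- matchPattern(reverseComplement(pat), subj, fixed = FALSE)
  rows <- list()
  if (length(fwd)) {
    rows$f <- data.frame(tl_position = start(fwd) - 1L, strand = "+",
                         matched_seq = as.character(fwd),
                         stringsAsFactors = FALSE)
  }
  if (length(rev_)) {
    rows$r <- data.frame(tl_position = start(rev_) - 1L, strand = "-",
                         matched_seq = as.character(rev_),
                         stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$tl_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene motif enrichment by Fisher's exact test
#'
#' One-sided FET on the proportional ratio of (hits in the TL / TL
#' length) versus (remaining hits / remaining length); the focal TL is
#' excluded from the background row to avoid double counting.
#'
#' @param hits_tl motif hits in the gene's TL.
#' @param len_tl TL length (nt), >= motif length.
#' @param total_hits motif hits over all TLs (including the focal one).
#' @param total_len summed TL length.
#' @param alpha significance level.
#' @return list: table, fold (TL rate over global rate),
#'   background_rate, p, enriched.
#' @export
perGeneFet <- function(hits_tl, len_tl, total_hits, total_len,
                       alpha = 0.05) {
  if (hits_tl > len_tl) stop("more hits than TL nucleotides")
  stopifnot(len_tl >= 8, total_hits >= hits_tl, total_len >= len_tl)
  other_hits <- total_hits - hits_tl
  tab <- matrix(c(hits_tl, len_tl - hits_tl,
                  other_hits, total_len - len_tl - other_hits),
                2, 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "greater")$p.value
  rate <- total_hits / total_len
  list(table = tab,
       fold = (hits_tl / len_tl) / rate,
       background_rate = rate, p = p, enriched = p < alpha)
}

#' Hypergeometric overlap enrichment of two gene sets
#'
#' With N genes in the universe, K in set B and n in set A, tests whether
#' the observed overlap k is higher than expected at random:
#' p = P(X >= k), fold = (k/n)/(K/N).
#'
#' @param k overlap size.
#' @param n size of set A.
#' @param K size of set B.
#' @param N universe size.
#' @return list: k, n, K, N, fold, expected, p.
#' @export
hypergeomOverlap <- function(k, n, K, N) {
  if (k > min(n, K) || n > N || K > N || k < 0) {
    stop("impossible overlap counts")
  }
  list(k = k, n = n, K = K, N = N,
       fold = (k / n) / (K / N),
       expected = n * K / N,
       p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Relative-distance co-occurrence test between two feature sets
#'
#' For each A feature lying between two B features in the same TL, the
#' relative distance d in [0, 0.5] is the distance to the nearest B
#' divided by the spacing of the flanking B pair. Under independence d is
#' uniform on [0, 0.5]; co-occurrence shows up as mass near 0. Tested by
#' Kolmogorov-Smirnov against the uniform plus a permutation p-value in
#' which B positions are redrawn uniformly within their TLs.
#'
#' @param positions_a,positions_b named lists (per gene) of 0-based TL
#'   positions. TLs with fewer than 2 B features are skipped.
#' @param tl_lengths named TL lengths.
#' @param seed integer seed for the permutation null.
#' @param n_perm number of permutations.
#' @return list: n (A features scored), mean_d, ks_stat, ks_p, perm_p;
#'   or reason when no TL is eligible.
#' @export
reldistCooccurrence <- function(positions_a, positions_b, tl_lengths,
                                seed = 1L, n_perm = 100) {
  reld <- function(bpos_by_gene) {
    d <- numeric()
    for (g in names(positions_a)) {
      b <- sort(bpos_by_gene[[g]])
      if (length(b) < 2) next
      for (a in positions_a[[g]]) {
        if (a < b[1] || a > b[length(b)]) next
        i <- findInterval(a, b)
        if (b[i] == a) { d <- c(d, 0); next }
        gap <- b[i + 1L] - b[i]
        d <- c(d, min(a - b[i], b[i + 1L] - a) / gap)
      }
    }
    d
  }
  d_obs <- reld(positions_b)
  if (!length(d_obs)) {
    return(list(n = 0L, reason = "no TL with >= 2 B features and interior A"))
  }
  ks <- suppressWarnings(ks.test(d_obs, punif, min = 0, max = 0.5))
  set.seed(seed)
  stat_perm <- vapply(seq_len(n_perm), function(i) {
    bp <- lapply(names(positions_b), function(g) {
      nb <- length(positions_b[[g]])
      sort(sample.int(tl_lengths[[g]], nb) - 1L)
    })
    names(bp) <- names(positions_b)
    dp <- reld(bp)
    if (!length(dp)) return(NA_real_)
    suppressWarnings(ks.test(dp, punif, min = 0, max = 0.5))$statistic
  }, 0)
  stat_perm <- stat_perm[!is.na(stat_perm)]
  list(n = length(d_obs), mean_d = mean(d_obs),
       ks_stat = as.numeric(ks$statistic), ks_p = ks$p.value,
       perm_p = (1 + sum(stat_perm >= as.numeric(ks$statistic))) /
         (1 + length(stat_perm)))
}
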