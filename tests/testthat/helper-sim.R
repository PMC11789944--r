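# Shared small fixtures, built once per test run.

smallParams <- function(n_genes = 300, seed = 42, ...) {
  simulationParams(n_genes = n_genes, rng_seed = seed, ...)
}

# cache the default small simulation across test files
.simCache <- new.env(parent = emptyenv())

smallSim <- function() {
  if (is.null(.simCache$sim)) {
    .simCache$sim <- simulateExperiment(smallParams())
  }
  .simCache$sim
}

validatedFromTruth <- function(truth) {
  v <- truth[truth$has_uorf, c("gene_id", "uorf_start", "uorf_length")]
  names(v) <- c("gene_id", "tl_offset", "length")
  v
}

# independent exhaustive-enumeration oracles for 2x2 exact tests
fetOracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  ks <- max(0, k - n2):min(k, m)
  pmf <- choose(m, ks) * choose(n2, k - ks) / choose(m + n2, k)
  dobs <- choose(m, a) * choose(n2, c) / choose(m + n2, k)
  sum(pmf[pmf <= dobs * (1 + 1e-7)])
}

hyperUpperOracle <- function(k, n, K, N) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks) / choose(N, n))
}

# naive degenerate sliding-window motif oracle (forward + reverse strand)
motifOracle <- function(seq) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  match1 <- function(w, pat) {
    all(mapply(function(ch, p) switch(p,
      C = ch == "C", T = ch == "T", G = ch == "G", A = ch == "A",
      N = TRUE, Y = ch %in% c("C", "T"), R = ch %in% c("A", "G")),
      w, pat))
  }
  fwd <- c("C", "N", "Y", "T", "C", "N", "Y", "T")
  rev_ <- c("A", "R", "N", "G", "A", "R", "N", "G") # revcomp of CNYTCNYT
  out <- list()
  if (length(s) >= 8) {
    for (i in 1:(length(s) - 7)) {
      w <- s[i:(i + 7)]
      if (match1(w, fwd)) out[[length(out) + 1]] <- c(i - 1L, 1L)
      if (match1(w, rev_)) out[[length(out) + 1]] <- c(i - 1L, -1L)
    }
  }
  if (!length(out)) return(data.frame(pos = integer(), strand = integer()))
  m <- do.call(rbind, out)
  data.frame(pos = m[, 1], strand = m[, 2])
}
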