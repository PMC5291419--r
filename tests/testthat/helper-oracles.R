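# Independent brute-force oracles. These deliberately share no code with
# the package: string reverse complement via chartr, scores via explicit
# loops over positions, BH via the raw step-up definition.

BASES <- c("A", "C", "G", "T")

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# freq: L x 4 matrix, columns A,C,G,T
oracle_matching_score <- function(freq, kmer) {
  ch <- strsplit(kmer, "")[[1]]
  s <- 0; smin <- 0; smax <- 0
  for (i in seq_along(ch)) {
    s <- s + freq[i, match(ch[i], BASES)]
    smin <- smin + min(freq[i, ])
    smax <- smax + max(freq[i, ])
  }
  if (smax == smin) 1 else (s - smin) / (smax - smin)
}

oracle_dissimilarity <- function(freq, kmer) {
  100 * (1 - oracle_matching_score(freq, kmer))
}

# All hits (offset 0-based, strand, dissimilarity) with dissimilarity
# strictly below the threshold, both strands, windows with non-ACGT skipped.
oracle_scan <- function(freq, seq, max_dissimilarity, strands = "both") {
  L <- nrow(freq)
  n <- nchar(seq)
  rows <- list()
  if (n >= L) {
    for (off in 0:(n - L)) {
      w <- substr(seq, off + 1, off + L)
      if (grepl("[^ACGT]", w)) next
      strands_here <- if (strands == "both") c("+", "-") else "+"
      for (st in strands_here) {
        k <- if (st == "+") w else oracle_revcomp(w)
        d <- oracle_dissimilarity(freq, k)
        if (d < max_dissimilarity) {
          rows[[length(rows) + 1]] <- data.frame(
            offset = off, strand = st, kmer = k, dissimilarity = d,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      kmer = character(), dissimilarity = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Expected number of sub-threshold hits per scanned window pair (both
# strands) on uniform-random background, by exhaustive enumeration of all
# 4^L k-mers.
oracle_expected_hits_per_window <- function(freq, max_dissimilarity) {
  L <- nrow(freq)
  kmers <- do.call(expand.grid, rep(list(BASES), L))
  total <- 0
  for (r in seq_len(nrow(kmers))) {
    k <- paste(unlist(kmers[r, ]), collapse = "")
    hit_fwd <- oracle_dissimilarity(freq, k) < max_dissimilarity
    hit_rev <- oracle_dissimilarity(freq, oracle_revcomp(k)) < max_dissimilarity
    total <- total + (hit_fwd + hit_rev) / 4^L
  }
  total
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)  # rank of p[i] among sorted values
    cands <- sapply(rank_i:n, function(j) p[ord[j]] * n / j)
    adj[i] <- min(1, min(cands))
  }
  adj
}

oracle_one_sample_t <- function(x) {
  n <- length(x)
  t <- mean(x) / (sd(x) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Frequency matrix with a unique per-position argmax, drawn from a
# Dirichlet-like construction; returns plain matrix.
random_freq_matrix <- function(L) {
  m <- matrix(rexp(4 * L), nrow = L)
  m <- m / rowSums(m)
  colnames(m) <- BASES
  m
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
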