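#' Position weight matrices
#'
#' A `pwm` object holds a motif as an L x 4 numeric matrix over the DNA
#' alphabet (columns `A`, `C`, `G`, `T`; one row per motif position). Two
#' kinds exist: `"counts"` (nonnegative observation counts, every position
#' summing to more than zero) and `"frequency"` (per-position base
#' frequencies summing to one). Scoring always happens on the frequency
#' kind; [pwm_frequencies()] converts counts with an optional pseudocount.
#'
#' @param values L x 4 numeric matrix (or anything coercible) with one row
#'   per motif position; columns are taken in A, C, G, T order. Column
#'   names, if present, must be a permutation of A, C, G, T and are used
#'   to reorder.
#' @param kind `"counts"` or `"frequency"`.
#' @param name Free-text motif name.
#' @param source_format Provenance tag, one of `"jaspar"`, `"transfac"`,
#'   `"inline"`.
#' @return An object of class `pwm`.
#' @examples
#' m <- pwm(rbind(c(8, 0, 1, 1), c(1, 7, 1, 1)), kind = "counts", name = "toy")
#' pwm_frequencies(m)
#' @export
pwm <- function(values, kind = c("frequency", "counts"), name = "motif",
                source_format = "inline") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values) || ncol(values) != 4L || nrow(values) < 1L) {
    stop("`values` must be a numeric L x 4 matrix with L >= 1", call. = FALSE)
  }
  if (!is.null(colnames(values))) {
    if (!setequal(colnames(values), DNA_BASES)) {
      stop("matrix column names must be A, C, G, T", call. = FALSE)
    }
    values <- values[, DNA_BASES, drop = FALSE]
  } else {
    colnames(values) <- DNA_BASES
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("matrix values must be finite and nonnegative", call. = FALSE)
  }
  sums <- rowSums(values)
  if (kind == "counts" && any(sums <= 0)) {
    stop("counts matrix has an all-zero position", call. = FALSE)
  }
  if (kind == "frequency") {
    if (any(abs(sums - 1) > 1e-9)) {
      stop("frequency matrix positions must each sum to 1", call. = FALSE)
    }
    if (any(values > 1 + 1e-12)) {
      stop("frequency values must lie in [0, 1]", call. = FALSE)
    }
  }
  rownames(values) <- NULL
  structure(
    list(values = values, kind = kind, name = name,
         source_format = source_format),
    class = "pwm"
  )
}

DNA_BASES <- c("A", "C", "G", "T")

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s [%s, %d positions, %s]\n",
              x$name, x$kind, motif_length(x), x$source_format))
  print(round(x$values, 4))
  invisible(x)
}

#' Motif length (number of positions) of a PWM
#' @param x A [pwm] object.
#' @return Integer motif length L.
#' @export
motif_length <- function(x) {
  stopifnot(inherits(x, "pwm"))
  nrow(x$values)
}

#' Convert a count matrix to a frequency matrix
#'
#' Each position is normalised to frequencies
#' `(count + pseudocount) / (position_sum + 4 * pseudocount)`. The default
#' pseudocount of 0.2 per base (0.8 per position) follows common practice
#' for count matrices; frequency matrices pass through unchanged when
#' `pseudocount = 0`.
#'
#' @param x A [pwm] object.
#' @param pseudocount Nonnegative pseudocount added per base. Default 0.2
#'   for counts input, 0 for frequency input.
#' @return A frequency-kind [pwm]. The pseudocount used is recorded in the
#'   `pseudocount` attribute.
#' @export
pwm_frequencies <- function(x, pseudocount = NULL) {
  stopifnot(inherits(x, "pwm"))
  if (is.null(pseudocount)) {
    pseudocount <- if (x$kind == "counts") 0.2 else 0
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      is.na(pseudocount) || pseudocount < 0) {
    stop("`pseudocount` must be a single nonnegative number", call. = FALSE)
  }
  v <- x$values
  if (x$kind == "frequency" && pseudocount == 0) {
    return(x)
  }
  sums <- rowSums(v)
  if (pseudocount == 0 && any(sums <= 0)) {
    stop("degenerate all-zero position with pseudocount 0", call. = FALSE)
  }
  freq <- (v + pseudocount) / (sums + 4 * pseudocount)
  out <- pwm(freq, kind = "frequency", name = x$name,
             source_format = x$source_format)
  attr(out, "pseudocount") <- pseudocount
  out
}

as_frequency_pwm <- function(x) {
  if (x$kind == "frequency") x else pwm_frequencies(x)
}

#' Consensus sequence of a PWM
#'
#' The k-mer taking each position's maximal base; ties are broken
#' alphabetically (A < C < G < T) so the result is deterministic.
#'
#' @param x A [pwm] object (counts are converted with the default
#'   pseudocount first; the argmax is unaffected by uniform pseudocounts).
#' @return A single DNA string of length `motif_length(x)`.
#' @export
pwm_consensus <- function(x) {
  v <- as_frequency_pwm(x)$values
  paste(DNA_BASES[apply(v, 1L, which.max)], collapse = "")
}

## Integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else NA.
encode_dna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
  codes
}

#' Matching score of a k-mer against a PWM
#'
#' The raw score is the sum over positions of the matrix frequency of the
#' observed base. It is min-max normalised to `[0, 1]`:
#' `(S - S_min) / (S_max - S_min)` where `S_min` and `S_max` sum the
#' per-position minima and maxima. The consensus scores 1, the worst
#' possible window 0. A fully uniform matrix (where `S_max == S_min`)
#' scores 1 by convention. [dissimilarity()] is `100 * (1 - score)`, the
#' percent scale on which 0% means identity to the consensus.
#'
#' @param x A [pwm] object; counts are converted with the default
#'   pseudocount.
#' @param kmer Character vector of DNA strings, each of length
#'   `motif_length(x)` over A/C/G/T only (ambiguity codes are rejected).
#' @param information_weighted If `TRUE`, positions are weighted by their
#'   information content (bits) before normalisation, so conserved
#'   positions dominate the score. Default `FALSE`.
#' @return Numeric vector of scores in `[0, 1]` (or percent in
#'   `[0, 100]` for `dissimilarity()`).
#' @examples
#' m <- pwm(rbind(c(.7, .1, .1, .1), c(.4, .4, .1, .1)))
#' matching_score(m, "AG")   # 0.6667
#' dissimilarity(m, "AA")    # 0: "AA" is the consensus
#' @export
matching_score <- function(x, kmer, information_weighted = FALSE) {
  stopifnot(inherits(x, "pwm"))
  v <- as_frequency_pwm(x)$values
  if (isTRUE(information_weighted)) {
    v <- v * pwm_position_ic(v)
  }
  L <- nrow(v)
  s_min <- sum(apply(v, 1L, min))
  s_max <- sum(apply(v, 1L, max))
  vapply(kmer, function(k) {
    codes <- encode_dna(k)
    if (length(codes) != L) {
      stop(sprintf("k-mer length %d does not match motif length %d",
                   length(codes), L), call. = FALSE)
    }
    if (anyNA(codes)) {
      stop("k-mer contains a non-ACGT symbol", call. = FALSE)
    }
    s <- sum(v[cbind(seq_len(L), codes)])
    if (s_max == s_min) 1 else (s - s_min) / (s_max - s_min)
  }, numeric(1), USE.NAMES = FALSE)
}

## Per-position information content in bits (2 + sum f log2 f), used by the
## optional information-weighted score.
pwm_position_ic <- function(v) {
  plogp <- ifelse(v > 0, v * log2(v), 0)
  2 + rowSums(plogp)
}

#' @rdname matching_score
#' @export
dissimilarity <- function(x, kmer, information_weighted = FALSE) {
  100 * (1 - matching_score(x, kmer, information_weighted))
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()];
#' accepts A/C/G/T/N (case-insensitive, returned upper case).
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("sequence contains symbols outside A/C/G/T/N", call. = FALSE)
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

## PWM for scanning the minus strand: reverse the positions and swap
## complementary base columns, so forward windows can be scored in place.
reverse_complement_pwm <- function(x) {
  v <- x$values[rev(seq_len(nrow(x$values))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(v) <- DNA_BASES
  pwm(v, kind = x$kind, name = x$name, source_format = x$source_format)
}

#' Sequence-logo columns: information content and letter heights
#'
#' For aligned, equal-length binding sites, computes per-column base
#' frequencies, information content `IC = 2 + sum_b f_b log2 f_b` bits
#' (with `0 log 0 := 0`), and letter heights `f_b * IC` — the quantities a
#' sequence logo draws, where the overall column height reflects the
#' degree of conservation. The optional small-sample correction subtracts
#' `e(n) = 3 / (2 ln(2) n)` from the IC (floored at zero).
#'
#' @param sites Character vector of equal-length A/C/G/T strings (at least
#'   one).
#' @param small_sample_correction Apply the `e(n)` correction. Default
#'   `FALSE`.
#' @return A tibble with one row per column: `position` (1-based),
#'   `freq_A` .. `freq_T`, `ic_bits`, `height_A` .. `height_T`.
#' @examples
#' logo_columns(c("ACGT", "ACGA", "ACTT"))
#' @export
logo_columns <- function(sites, small_sample_correction = FALSE) {
  if (length(sites) < 1L) stop("need at least one site", call. = FALSE)
  sites <- toupper(sites)
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) {
    stop("sites must all have equal length", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", sites))) {
    stop("sites must contain only A/C/G/T", call. = FALSE)
  }
  n <- length(sites)
  L <- lens[1]
  chars <- matrix(unlist(strsplit(sites, "", fixed = TRUE)),
                  nrow = n, ncol = L, byrow = TRUE)
  purrr::map_dfr(seq_len(L), function(j) {
    f <- vapply(DNA_BASES, function(b) mean(chars[, j] == b), numeric(1))
    ic <- 2 + sum(ifelse(f > 0, f * log2(f), 0))
    if (isTRUE(small_sample_correction)) {
      ic <- max(0, ic - 3 / (2 * log(2) * n))
    }
    tibble::tibble(
      position = j,
      freq_A = f[["A"]], freq_C = f[["C"]], freq_G = f[["G"]], freq_T = f[["T"]],
      ic_bits = ic,
      height_A = f[["A"]] * ic, height_C = f[["C"]] * ic,
      height_G = f[["G"]] * ic, height_T = f[["T"]] * ic
    )
  })
}

#' Write logo columns to TSV
#'
#' @param logo Tibble from [logo_columns()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  readr::write_tsv(logo, path)
  invisible(path)
}
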