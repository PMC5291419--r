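#' Scan a sequence for PWM matches
#'
#' Scores every length-L window of `sequence` (and, by default, its
#' reverse complement) against the matrix and reports windows whose
#' dissimilarity rate is strictly below `max_dissimilarity`. Windows
#' containing a non-ACGT base are skipped, not scored; the number of
#' skipped window positions is available as the `skipped_windows`
#' attribute of the result, and the minimum dissimilarity over all scored
#' windows (regardless of threshold) as `best_dissimilarity`.
#'
#' Minus-strand hits report the offset of the matched window on the
#' forward sequence; the `kmer` column always gives the matched word read
#' 5'->3' on the hit's own strand.
#'
#' @param x A [pwm] object.
#' @param sequence A single DNA string (may contain N; may be shorter
#'   than the motif, in which case no windows exist).
#' @param max_dissimilarity Report hits with dissimilarity strictly below
#'   this percent threshold (0-100). Default 100 reports every scored
#'   window.
#' @param strands `"both"` (default) or `"plus"`.
#' @param information_weighted Passed to [matching_score()].
#' @return Tibble sorted by `(offset, strand)` with columns `offset`
#'   (0-based), `strand`, `kmer`, `raw_score`, `matching_score`,
#'   `dissimilarity`; attributes `skipped_windows`, `n_scored`,
#'   `best_dissimilarity` (NA when nothing was scorable).
#' @examples
#' m <- pwm(rbind(c(1, 0, 0, 0), c(0, 0, 1, 0), c(1, 0, 0, 0)))  # "AGA"
#' scan_sequence(m, "TTAGATT", max_dissimilarity = 5)
#' @export
scan_sequence <- function(x, sequence, max_dissimilarity = 100,
                          strands = c("both", "plus"),
                          information_weighted = FALSE) {
  strands <- match.arg(strands)
  stopifnot(inherits(x, "pwm"), length(sequence) == 1L)
  if (!is.numeric(max_dissimilarity) || max_dissimilarity < 0 ||
      max_dissimilarity > 100) {
    stop("`max_dissimilarity` must lie in [0, 100]", call. = FALSE)
  }
  fw <- as_frequency_pwm(x)
  v <- fw$values
  if (isTRUE(information_weighted)) v <- v * pwm_position_ic(fw$values)
  L <- nrow(v)
  seq_up <- toupper(sequence)
  codes <- if (nchar(seq_up)) encode_dna(seq_up) else integer(0)
  n_win <- length(codes) - L + 1L
  empty <- tibble::tibble(
    offset = integer(), strand = character(), kmer = character(),
    raw_score = numeric(), matching_score = numeric(), dissimilarity = numeric()
  )
  if (n_win < 1L) {
    return(scan_result(empty, skipped = 0L, n_scored = 0L, best = NA_real_))
  }

  s_min <- sum(apply(v, 1L, min))
  s_max <- sum(apply(v, 1L, max))
  span <- s_max - s_min

  ## raw score of every forward window against a (possibly rc'd) matrix,
  ## vectorised over offsets: one pass per motif position
  window_scores <- function(mat) {
    s <- numeric(n_win)
    for (p in seq_len(L)) {
      s <- s + mat[p, ][codes[seq_len(n_win) + (p - 1L)]]
    }
    unname(s)  # NA where the window holds a non-ACGT base
  }
  to_match <- function(s) if (span == 0) rep(1, length(s)) else (s - s_min) / span

  raw_plus <- window_scores(v)
  scorable <- !is.na(raw_plus)
  skipped <- sum(!scorable)
  offs <- which(scorable) - 1L
  if (length(offs) == 0L) {
    return(scan_result(empty, skipped = skipped, n_scored = 0L,
                       best = NA_real_))
  }
  words <- substring(seq_up, offs + 1L, offs + L)

  hit_rows <- function(raw, strand, kmer) {
    match <- to_match(raw)
    tibble::tibble(
      offset = offs, strand = strand, kmer = kmer,
      raw_score = raw, matching_score = match,
      dissimilarity = 100 * (1 - match)
    )
  }
  hits <- hit_rows(raw_plus[scorable], "+", words)
  if (strands == "both") {
    rc <- reverse_complement_pwm(fw)
    vrc <- rc$values
    if (isTRUE(information_weighted)) vrc <- vrc * pwm_position_ic(rc$values)
    raw_minus <- window_scores(vrc)
    hits_minus <- hit_rows(raw_minus[scorable], "-", reverse_complement(words))
    hits <- dplyr::bind_rows(hits, hits_minus)
  }
  best <- if (nrow(hits)) min(hits$dissimilarity) else NA_real_
  hits <- dplyr::arrange(
    dplyr::filter(hits, .data$dissimilarity < max_dissimilarity),
    .data$offset, .data$strand
  )
  scan_result(hits, skipped = skipped,
              n_scored = sum(scorable) * (if (strands == "both") 2L else 1L),
              best = best)
}

scan_result <- function(hits, skipped, n_scored, best) {
  attr(hits, "skipped_windows") <- as.integer(skipped)
  attr(hits, "n_scored") <- as.integer(n_scored)
  attr(hits, "best_dissimilarity") <- best
  hits
}

#' Scan a promoter set and summarise per promoter
#'
#' `scan_promoters()` runs [scan_sequence()] over every row of a promoter
#' tibble and returns all sub-threshold hits, keyed by promoter and gene.
#' `scan_summary()` returns the per-promoter roll-up used for candidate
#' classification: the best (minimum) dissimilarity over all scored
#' windows — not only sub-threshold ones — the count of hits strictly
#' below the threshold, and the tally of windows skipped for ambiguous
#' bases.
#'
#' @param promoters Tibble with columns `promoter_id`, `gene_id`,
#'   `sequence` (as produced by [extract_promoters()] or
#'   [simulate_promoters()]; any tibble with those columns works, and a
#'   `name`/`sequence` FASTA tibble is accepted by treating `name` as
#'   both ids).
#' @param x A [pwm] object.
#' @inheritParams scan_sequence
#' @return `scan_promoters()`: tibble `promoter_id`, `gene_id`, `offset`,
#'   `strand`, `kmer`, `matching_score`, `dissimilarity`.
#'   `scan_summary()`: tibble `gene_id`, `promoter_id`,
#'   `best_dissimilarity` (NA when no window was scorable), `n_hits`,
#'   `skipped_windows`.
#' @export
scan_promoters <- function(promoters, x, max_dissimilarity = 100,
                           strands = c("both", "plus"),
                           information_weighted = FALSE) {
  strands <- match.arg(strands)
  promoters <- normalize_promoters(promoters)
  purrr::pmap_dfr(
    promoters[, c("promoter_id", "gene_id", "sequence")],
    function(promoter_id, gene_id, sequence) {
      hits <- scan_sequence(x, sequence, max_dissimilarity, strands,
                            information_weighted)
      if (nrow(hits) == 0L) return(NULL)
      dplyr::mutate(
        dplyr::select(hits, -"raw_score"),
        promoter_id = promoter_id, gene_id = gene_id, .before = 1
      )
    }
  )
}

#' @rdname scan_promoters
#' @export
scan_summary <- function(promoters, x, max_dissimilarity = 5,
                         strands = c("both", "plus"),
                         information_weighted = FALSE) {
  strands <- match.arg(strands)
  promoters <- normalize_promoters(promoters)
  purrr::pmap_dfr(
    promoters[, c("promoter_id", "gene_id", "sequence")],
    function(promoter_id, gene_id, sequence) {
      hits <- scan_sequence(x, sequence, max_dissimilarity, strands,
                            information_weighted)
      tibble::tibble(
        gene_id = gene_id, promoter_id = promoter_id,
        best_dissimilarity = attr(hits, "best_dissimilarity"),
        n_hits = nrow(hits),
        skipped_windows = attr(hits, "skipped_windows")
      )
    }
  )
}

normalize_promoters <- function(promoters) {
  stopifnot(is.data.frame(promoters))
  if (!"sequence" %in% names(promoters)) {
    stop("promoter table needs a `sequence` column", call. = FALSE)
  }
  if (!"promoter_id" %in% names(promoters)) {
    if (!"name" %in% names(promoters)) {
      stop("promoter table needs `promoter_id` (or FASTA `name`) column",
           call. = FALSE)
    }
    promoters$promoter_id <- promoters$name
  }
  if (!"gene_id" %in% names(promoters)) promoters$gene_id <- promoters$promoter_id
  promoters
}

#' Classify candidate genes at a dissimilarity threshold
#'
#' A gene is a candidate when any of its promoters has a best
#' dissimilarity strictly below the threshold (the "less than 5%" rule;
#' genes with several promoters pass if any single promoter passes).
#'
#' @param summaries Tibble from [scan_summary()].
#' @param max_dissimilarity Percent threshold; strict `<` comparison.
#' @return Sorted character vector of candidate `gene_id`s.
#' @export
classify_candidates <- function(summaries, max_dissimilarity = 5) {
  stopifnot(is.data.frame(summaries),
            all(c("gene_id", "best_dissimilarity") %in% names(summaries)))
  pass <- dplyr::filter(summaries,
                        !is.na(.data$best_dissimilarity),
                        .data$best_dissimilarity < max_dissimilarity)
  sort(unique(pass$gene_id))
}

#' Filter a two-species target table at a shared threshold
#'
#' Keeps genes whose dissimilarity scores are present and strictly below
#' the threshold in both species columns; a missing (`N/A`) score fails
#' the filter.
#'
#' @param rows Tibble from [read_target_table()] (columns `gene_symbol`,
#'   `score_a`, `score_b`).
#' @param max_dissimilarity Percent threshold; strict `<`.
#' @return Sorted character vector of passing gene symbols.
#' @export
both_species_filter <- function(rows, max_dissimilarity = 5) {
  stopifnot(is.data.frame(rows),
            all(c("gene_symbol", "score_a", "score_b") %in% names(rows)))
  pass <- dplyr::filter(rows,
                        !is.na(.data$score_a), !is.na(.data$score_b),
                        .data$score_a < max_dissimilarity,
                        .data$score_b < max_dissimilarity)
  sort(unique(pass$gene_symbol))
}

#' Overlap two gene lists
#'
#' Gene symbols are normalised (trimmed, upper-cased) before comparison
#' and partitioned into list-A-only, list-B-only and shared sets.
#'
#' @param list_a,list_b Character vectors of gene symbols.
#' @return An `overlap_summary` object: a list with sorted character
#'   vectors `only_a`, `only_b`, `shared`. Has [generics::tidy()] and
#'   `print()` methods.
#' @examples
#' overlap_sets(c("a", "B", "C"), c("b", "c", "d"))
#' @export
overlap_sets <- function(list_a, list_b) {
  a <- unique(toupper(trimws(as.character(list_a))))
  b <- unique(toupper(trimws(as.character(list_b))))
  a <- a[nzchar(a)]; b <- b[nzchar(b)]
  structure(
    list(only_a = sort(setdiff(a, b)),
         only_b = sort(setdiff(b, a)),
         shared = sort(intersect(a, b))),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> shared %d | only A %d | only B %d\n",
              length(x$shared), length(x$only_a), length(x$only_b)))
  invisible(x)
}

#' @rdname overlap_sets
#' @param x An `overlap_summary` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.overlap_summary <- function(x, ...) {
  tibble::tibble(
    gene = c(x$shared, x$only_a, x$only_b),
    set = rep(c("shared", "only_a", "only_b"),
              c(length(x$shared), length(x$only_a), length(x$only_b)))
  )
}

#' Write scanner outputs
#'
#' Plain-TSV writers for the hits and summary tables and a one-symbol-
#' per-line writer for candidate gene lists.
#'
#' @param hits,summaries Tibbles from [scan_promoters()] /
#'   [scan_summary()].
#' @param genes Character vector of gene symbols.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_summary_tsv <- function(summaries, path) {
  readr::write_tsv(summaries, path)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_gene_list <- function(genes, path) {
  readr::write_lines(genes, path)
  invisible(path)
}
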