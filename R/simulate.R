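#' Seeded random DNA sequence
#'
#' Draws bases i.i.d. from the given composition using R's Mersenne
#' Twister stream; a fixed seed gives a bit-identical sequence. When
#' `seed` is `NULL` the caller's RNG state is used (and advanced).
#'
#' @param length Sequence length (>= 0).
#' @param base_probs Four nonnegative weights for A, C, G, T (sum > 0;
#'   normalised internally). Default uniform.
#' @param seed Optional integer seed; applied locally so the global RNG
#'   state is untouched.
#' @return A single DNA string.
#' @examples
#' random_sequence(10, seed = 1)
#' @export
random_sequence <- function(length, base_probs = c(0.25, 0.25, 0.25, 0.25),
                            seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 0) stop("`length` must be >= 0", call. = FALSE)
  if (!is.numeric(base_probs) || length(base_probs) != 4L ||
      any(!is.finite(base_probs)) || any(base_probs < 0) ||
      sum(base_probs) <= 0) {
    stop("`base_probs` must be 4 nonnegative weights with positive sum",
         call. = FALSE)
  }
  if (length == 0L) return("")
  draw <- function() {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = base_probs),
          collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Plant a motif site into a sequence
#'
#' Overwrites (never inserts, so coordinates stay stable) the bases at
#' `[offset, offset + L)` with either the matrix consensus or a site
#' sampled per position from the matrix frequencies.
#'
#' @param sequence A single DNA string.
#' @param x A [pwm] object.
#' @param offset 0-based start of the planted site;
#'   `offset + motif_length(x)` must not exceed the sequence length.
#' @param mode `"consensus"` (default) or `"sampled"`.
#' @param seed Optional integer seed for sampled mode.
#' @return List with `sequence` (the modified string) and `truth`, a
#'   one-row tibble (`offset`, `strand`, `mode`, `planted_kmer`).
#' @export
plant_motif <- function(sequence, x, offset, mode = c("consensus", "sampled"),
                        seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "pwm"), length(sequence) == 1L)
  L <- motif_length(x)
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0 || offset + L > nchar(sequence)) {
    stop("planted site does not fit the sequence at this offset", call. = FALSE)
  }
  kmer <- if (mode == "consensus") {
    pwm_consensus(x)
  } else {
    v <- as_frequency_pwm(x)$values
    draw <- function() {
      paste(vapply(seq_len(L), function(p) {
        sample(DNA_BASES, 1L, prob = v[p, ])
      }, character(1)), collapse = "")
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  out <- sequence
  substr(out, offset + 1L, offset + L) <- kmer
  list(
    sequence = out,
    truth = tibble::tibble(offset = offset, strand = "+", mode = mode,
                           planted_kmer = kmer)
  )
}

#' Simulate a promoter set with planted motif sites
#'
#' Generates `n` random promoters and plants one motif site (consensus
#' or matrix-sampled) into the first `n_planted` of them at uniformly
#' drawn offsets. The defaults mirror the reduced-scale benchmark used
#' throughout the package's tests: 200 promoters of 1000 bp with 60
#' planted consensus sites.
#'
#' @param x A [pwm] object.
#' @param n Number of promoters.
#' @param length Promoter length in bases.
#' @param n_planted Number of promoters that receive a planted site
#'   (`<= n`).
#' @param mode `"consensus"` or `"sampled"` (see [plant_motif()]).
#' @param base_probs Background base composition.
#' @param seed Integer seed; the whole set is reproducible from it.
#' @return List with `promoters` (tibble `promoter_id`, `gene_id`,
#'   `sequence`, `planted`) and `truth` (one row per planted site:
#'   `promoter_id`, `offset`, `strand`, `mode`, `planted_kmer`).
#' @export
simulate_promoters <- function(x, n = 200, length = 1000, n_planted = 60,
                               mode = c("consensus", "sampled"),
                               base_probs = c(0.25, 0.25, 0.25, 0.25),
                               seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "pwm"))
  n <- as.integer(n); n_planted <- as.integer(n_planted)
  if (n_planted > n) stop("`n_planted` cannot exceed `n`", call. = FALSE)
  L <- motif_length(x)
  if (length < L) stop("promoters must be at least one motif long", call. = FALSE)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) random_sequence(length, base_probs),
                   character(1))
    ids <- sprintf("prom_%03d", seq_len(n))
    truth <- purrr::map_dfr(seq_len(n_planted), function(i) {
      offset <- sample.int(length - L + 1L, 1L) - 1L
      planted <- plant_motif(seqs[i], x, offset, mode)
      seqs[i] <<- planted$sequence
      dplyr::mutate(planted$truth, promoter_id = ids[i], .before = 1)
    })
    list(
      promoters = tibble::tibble(
        promoter_id = ids, gene_id = ids, sequence = seqs,
        planted = seq_len(n) <= n_planted
      ),
      truth = truth
    )
  })
}

#' Simulate a replicate qPCR Ct table around a known RQ
#'
#' Builds control/treated Ct pairs whose noiseless inversion through
#' [rq_from_ct()] recovers `true_rq` exactly: the reference assay has
#' equal Ct in both conditions, and the treated target Ct is shifted by
#' `-log(true_rq)/log(e_target)` cycles from the control baseline.
#' Gaussian noise of sd `noise_sd` is then added independently to every
#' Ct value.
#'
#' @param true_rq True relative quantity (> 0).
#' @param e_target,e_reference Amplification efficiencies in `(1, 2]`.
#' @param ct_baseline Control-condition Ct baseline in cycles.
#' @param noise_sd Per-Ct Gaussian noise sd in cycles (0 for noiseless).
#' @param n_replicates Number of replicates (>= 2).
#' @param gene,seed Gene label and integer seed.
#' @return Tibble in the [rq_from_ct()] input layout.
#' @examples
#' ct <- simulate_ct_table(true_rq = 2, noise_sd = 0, n_replicates = 3)
#' rq_from_ct(ct)$rq  # exactly 2 2 2
#' @export
simulate_ct_table <- function(true_rq = 2, e_target = 2, e_reference = 2,
                              ct_baseline = 25, noise_sd = 0.1,
                              n_replicates = 3, gene = "target",
                              seed = NULL) {
  if (!is.finite(true_rq) || true_rq <= 0) stop("`true_rq` must be > 0", call. = FALSE)
  check_efficiency(e_target); check_efficiency(e_reference)
  if (n_replicates < 2L) stop("need at least two replicates", call. = FALSE)
  build <- function() {
    shift <- log(true_rq) / log(e_target)
    reps <- sprintf("r%02d", seq_len(n_replicates))
    base <- tibble::tibble(
      gene = gene,
      replicate = rep(reps, each = 2L),
      condition = rep(c("control", "treated"), times = n_replicates),
      ct_target = rep(c(ct_baseline, ct_baseline - shift), times = n_replicates),
      ct_reference = ct_baseline,
      e_target = e_target, e_reference = e_reference
    )
    if (noise_sd > 0) {
      base$ct_target <- base$ct_target + stats::rnorm(nrow(base), 0, noise_sd)
      base$ct_reference <- base$ct_reference + stats::rnorm(nrow(base), 0, noise_sd)
    }
    base
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate a ChIP-qPCR Ct table around known percent-input values
#'
#' For each locus, sets the input Ct to `ct_baseline` and derives the IP
#' Ct so that the noiseless [percent_input()] equals the requested
#' truth, then adds Gaussian Ct noise.
#'
#' @param true_percent Named or unnamed vector of true percent-input
#'   values (> 0).
#' @param input_fraction Fraction of chromatin reserved as input
#'   (default 0.10, i.e. dilution factor 10).
#' @param ct_baseline Input Ct baseline.
#' @param noise_sd Per-Ct Gaussian noise sd.
#' @param seed Integer seed.
#' @return Tibble with columns `locus`, `ct_ip`, `ct_input`,
#'   `input_fraction`, `true_percent`.
#' @export
simulate_chip_table <- function(true_percent, input_fraction = 0.10,
                                ct_baseline = 25, noise_sd = 0,
                                seed = NULL) {
  if (any(!is.finite(true_percent)) || any(true_percent <= 0)) {
    stop("`true_percent` must be positive", call. = FALSE)
  }
  df <- 1 / input_fraction
  loci <- names(true_percent)
  if (is.null(loci)) loci <- sprintf("locus_%02d", seq_along(true_percent))
  build <- function() {
    adjusted_input <- ct_baseline - log2(df)
    ct_ip <- unname(adjusted_input - log2(true_percent / 100))
    out <- tibble::tibble(
      locus = loci, ct_ip = ct_ip, ct_input = ct_baseline,
      input_fraction = input_fraction,
      true_percent = unname(true_percent)
    )
    if (noise_sd > 0) {
      out$ct_ip <- out$ct_ip + stats::rnorm(nrow(out), 0, noise_sd)
      out$ct_input <- out$ct_input + stats::rnorm(nrow(out), 0, noise_sd)
    }
    out
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate an expression table with controlled class fractions
#'
#' Allocates genes deterministically to regulation classes in the
#' requested fractions (largest-remainder rounding; any remainder is
#' `not_significant`), then draws a signed log2 fold change inside each
#' class's fold window and an FDR-adjusted p-value on the correct side
#' of the 0.05 gate, so [classify_regulation()] on the noiseless table
#' recovers the truth labels exactly.
#'
#' @param n_genes Number of genes (>= 0).
#' @param fractions Named numeric vector over
#'   `up_2to5, up_gt5, down_2to5, down_gt5, unchanged` summing to at
#'   most 1; the remainder becomes `not_significant`.
#' @param gt5_max Upper linear fold bound used when drawing `*_gt5`
#'   changes (default 10).
#' @param seed Integer seed.
#' @return Tibble: `gene`, `log2fc`, `p_value`, `fdr_adjusted_p`,
#'   `true_class`.
#' @export
simulate_expression <- function(n_genes,
                                fractions = c(down_2to5 = 0.5, down_gt5 = 0.2),
                                gt5_max = 10, seed = 1) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 0) stop("`n_genes` must be >= 0", call. = FALSE)
  allowed <- setdiff(REGULATION_CLASSES, "not_significant")
  if (length(fractions)) {
    if (is.null(names(fractions)) || !all(names(fractions) %in% allowed)) {
      stop("`fractions` must be named with regulation classes: ",
           paste(allowed, collapse = ", "), call. = FALSE)
    }
    if (any(fractions < 0) || sum(fractions) > 1 + 1e-12) {
      stop("`fractions` must be nonnegative and sum to at most 1", call. = FALSE)
    }
  }
  counts <- largest_remainder(fractions, n_genes)
  classes <- c(rep(names(counts), counts),
               rep("not_significant", n_genes - sum(counts)))
  if (n_genes == 0L) {
    return(tibble::tibble(gene = character(), log2fc = numeric(),
                          p_value = numeric(), fdr_adjusted_p = numeric(),
                          true_class = character()))
  }
  withr::with_seed(seed, {
    fold <- vapply(classes, function(cl) {
      switch(cl,
        unchanged = stats::runif(1, 1, 2 - 1e-6),
        up_2to5 = , down_2to5 = stats::runif(1, 2, 5 - 1e-6),
        up_gt5 = , down_gt5 = stats::runif(1, 5, gt5_max),
        not_significant = stats::runif(1, 1, gt5_max)
      )
    }, numeric(1))
    sign <- ifelse(grepl("^down", classes), -1, 1)
    adj_p <- ifelse(classes == "not_significant",
                    stats::runif(n_genes, 0.051, 1),
                    stats::runif(n_genes, 1e-6, 0.049))
    tibble::tibble(
      gene = sprintf("gene_%04d", seq_len(n_genes)),
      log2fc = sign * log2(fold),
      p_value = pmin(adj_p, 1),  # raw p never exceeds its BH-adjusted value
      fdr_adjusted_p = adj_p,
      true_class = classes
    )
  })
}

largest_remainder <- function(fractions, n) {
  if (length(fractions) == 0L) return(integer(0))
  exact <- fractions * n
  counts <- floor(exact)
  left <- round(min(sum(fractions), 1) * n) - sum(counts)
  if (left > 0) {
    order_rem <- order(exact - counts, decreasing = TRUE)
    counts[order_rem[seq_len(left)]] <- counts[order_rem[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

#' Write a complete synthetic fixture bundle
#'
#' Materialises one seeded fixture of every kind under `dir`: planted
#' promoters (FASTA + truth TSV), the matrix (internal TSV), a qPCR Ct
#' table, a ChIP table, an expression table, and a `manifest.txt`
#' recording the seed and parameters (R's Mersenne Twister is the
#' generator for all draws).
#'
#' @param dir Output directory (created if needed).
#' @param x A [pwm] object.
#' @param seed Integer master seed; sub-seeds are derived from it.
#' @param n,length,n_planted,mode Passed to [simulate_promoters()].
#' @param true_rq,noise_sd,n_replicates Passed to [simulate_ct_table()].
#' @return Invisible character vector of the files written.
#' @export
write_fixture_bundle <- function(dir, x, seed = 1, n = 200, length = 1000,
                                 n_planted = 60, mode = "consensus",
                                 true_rq = 2, noise_sd = 0.1,
                                 n_replicates = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_promoters(x, n = n, length = length, n_planted = n_planted,
                            mode = mode, seed = seed)
  files <- c(
    promoters = file.path(dir, "promoters.fa"),
    truth = file.path(dir, "truth.tsv"),
    matrix = file.path(dir, "matrix.tsv"),
    qpcr = file.path(dir, "qpcr.tsv"),
    chip = file.path(dir, "chip.tsv"),
    expression = file.path(dir, "expression.tsv"),
    manifest = file.path(dir, "manifest.txt")
  )
  write_fasta(dplyr::rename(sim$promoters[, c("promoter_id", "sequence")],
                            name = "promoter_id"), files[["promoters"]])
  readr::write_tsv(sim$truth, files[["truth"]])
  write_pwm_tsv(x, files[["matrix"]])
  readr::write_tsv(simulate_ct_table(true_rq = true_rq, noise_sd = noise_sd,
                                     n_replicates = n_replicates,
                                     seed = seed + 1L),
                   files[["qpcr"]])
  readr::write_tsv(simulate_chip_table(c(mmp9_site = 5, control_site = 0.5),
                                       noise_sd = noise_sd, seed = seed + 2L),
                   files[["chip"]])
  readr::write_tsv(simulate_expression(200, seed = seed + 3L),
                   files[["expression"]])
  manifest <- c(
    sprintf("seed=%d", seed),
    "rng=mersenne-twister",
    sprintf("n_promoters=%d", n), sprintf("promoter_length=%d", length),
    sprintf("n_planted=%d", n_planted), sprintf("plant_mode=%s", mode),
    sprintf("motif=%s", x$name), sprintf("motif_length=%d", motif_length(x)),
    sprintf("true_rq=%g", true_rq), sprintf("noise_sd=%g", noise_sd),
    sprintf("n_replicates=%d", n_replicates),
    sprintf("timestamp=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  readr::write_lines(manifest, files[["manifest"]])
  invisible(unname(files))
}
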