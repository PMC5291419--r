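#' Efficiency-corrected relative quantity (RQ)
#'
#' The efficiency-corrected delta-Ct ratio
#' `RQ = E_target^dCt_target / E_reference^dCt_reference`, where each
#' `dCt = Ct(control) - Ct(treated)` and `E` is the per-cycle
#' amplification efficiency in `(1, 2]` (2 means perfect doubling). With
#' this orientation, RQ above 1 means higher expression in the treated
#' condition.
#'
#' @param delta_ct_target,delta_ct_reference Delta-Ct values in cycles
#'   (control minus treated), target and reference gene.
#' @param e_target,e_reference Amplification efficiencies in `(1, 2]`.
#' @return Numeric RQ values (dimensionless).
#' @examples
#' relative_quantity(1, 0)                 # 2
#' relative_quantity(2, 1, 1.9, 2)         # 1.805
#' @export
relative_quantity <- function(delta_ct_target, delta_ct_reference,
                              e_target = 2, e_reference = 2) {
  check_efficiency(e_target); check_efficiency(e_reference)
  if (any(!is.finite(delta_ct_target)) || any(!is.finite(delta_ct_reference))) {
    stop("delta-Ct values must be finite", call. = FALSE)
  }
  e_target^delta_ct_target / e_reference^delta_ct_reference
}

check_efficiency <- function(e) {
  if (any(!is.finite(e)) || any(e <= 1) || any(e > 2)) {
    stop("amplification efficiency must lie in (1, 2]", call. = FALSE)
  }
  invisible(e)
}

#' Per-replicate RQ from a long Ct table
#'
#' Pairs control and treated rows per `(gene, replicate)`, forms
#' delta-Ct values as control minus treated for both the target and the
#' reference assay, and applies [relative_quantity()].
#'
#' @param ct Tibble with columns `gene`, `replicate`, `condition`
#'   (`"control"` / `"treated"`), `ct_target`, `ct_reference`,
#'   `e_target`, `e_reference` ([read_qpcr_table()] produces this
#'   layout).
#' @return Tibble with one row per `(gene, replicate)`:
#'   `delta_ct_target`, `delta_ct_reference`, `rq`.
#' @export
rq_from_ct <- function(ct) {
  need <- c("gene", "replicate", "condition", "ct_target", "ct_reference",
            "e_target", "e_reference")
  stopifnot(is.data.frame(ct), all(need %in% names(ct)))
  if (!all(ct$condition %in% c("control", "treated"))) {
    stop("condition must be 'control' or 'treated'", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    ct, id_cols = c("gene", "replicate", "e_target", "e_reference"),
    names_from = "condition", values_from = c("ct_target", "ct_reference")
  )
  need_wide <- c("ct_target_control", "ct_target_treated",
                 "ct_reference_control", "ct_reference_treated")
  if (!all(need_wide %in% names(wide)) ||
      anyNA(wide[need_wide])) {
    stop("every (gene, replicate) needs one control and one treated row",
         call. = FALSE)
  }
  dplyr::transmute(
    wide,
    gene = .data$gene, replicate = .data$replicate,
    delta_ct_target = .data$ct_target_control - .data$ct_target_treated,
    delta_ct_reference = .data$ct_reference_control - .data$ct_reference_treated,
    rq = relative_quantity(.data$delta_ct_target, .data$delta_ct_reference,
                           .data$e_target, .data$e_reference)
  )
}

#' Two-tailed one-sample t-test on log2 RQ
#'
#' Replicate RQ values are log2-transformed and tested against a
#' population mean of zero (no expression change) with a two-tailed
#' one-sample Student's t-test. Replicate sets with zero variance do not
#' abort: they are flagged `degenerate_variance`, with p reported as 0
#' when the common value differs from RQ = 1 and as 1 when it equals it.
#'
#' @param rqs Numeric vector of at least two positive replicate RQ
#'   values.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Object of class `log2_rq_test` with elements `n`,
#'   `mean_log2_rq`, `estimate_rq` (geometric-mean RQ), `statistic`,
#'   `df`, `p_value`, `significant`, `direction` (`"up"`, `"down"`,
#'   `"none"`), `degenerate_variance`, `alpha`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' fit <- log2_rq_test(c(1.8, 2.1, 2.4))
#' tidy(fit)
#' @export
log2_rq_test <- function(rqs, alpha = 0.05) {
  rqs <- as.numeric(rqs)
  if (length(rqs) < 2L) stop("need at least two replicate RQ values", call. = FALSE)
  if (any(!is.finite(rqs)) || any(rqs <= 0)) {
    stop("RQ values must be positive and finite", call. = FALSE)
  }
  x <- log2(rqs)
  m <- mean(x)
  degenerate <- stats::sd(x) == 0
  if (degenerate) {
    statistic <- if (m == 0) NA_real_ else Inf * sign(m)
    p <- if (m == 0) 1 else 0
    df <- length(x) - 1L
  } else {
    ht <- stats::t.test(x, mu = 0, alternative = "two.sided")
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    df <- unname(ht$parameter)
  }
  structure(
    list(n = length(x), mean_log2_rq = m, estimate_rq = 2^m,
         statistic = statistic, df = df, p_value = p,
         significant = p <= alpha,
         direction = if (m > 0) "up" else if (m < 0) "down" else "none",
         degenerate_variance = degenerate, alpha = alpha),
    class = "log2_rq_test"
  )
}

#' @export
print.log2_rq_test <- function(x, ...) {
  cat(sprintf(
    "<log2_rq_test> n=%d  mean log2RQ=%.4f (RQ=%.3f)  t=%s  p=%.4g%s\n",
    x$n, x$mean_log2_rq, x$estimate_rq,
    ifelse(is.na(x$statistic), "NA", sprintf("%.3f", x$statistic)),
    x$p_value,
    if (x$degenerate_variance) "  [degenerate variance]" else ""
  ))
  invisible(x)
}

#' @rdname log2_rq_test
#' @param x A `log2_rq_test` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.log2_rq_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_log2_rq, estimate_rq = x$estimate_rq,
    statistic = x$statistic, p.value = x$p_value, parameter = x$df
  )
}

#' @rdname log2_rq_test
#' @exportS3Method generics::glance
glance.log2_rq_test <- function(x, ...) {
  tibble::tibble(
    n = x$n, statistic = x$statistic, p.value = x$p_value,
    significant = x$significant, direction = x$direction,
    degenerate_variance = x$degenerate_variance
  )
}

#' Per-gene RQ tests over a replicate RQ table
#'
#' Groups a replicate-level RQ table by gene and applies
#' [log2_rq_test()] to each group.
#'
#' @param rq_tbl Tibble from [rq_from_ct()] (columns `gene`, `rq`).
#' @param alpha Significance level.
#' @return Tibble: `gene`, `n`, `mean_log2_rq`, `rq`, `statistic`,
#'   `p_value`, `significant`, `direction`, `degenerate_variance`.
#' @export
test_rq <- function(rq_tbl, alpha = 0.05) {
  stopifnot(is.data.frame(rq_tbl), all(c("gene", "rq") %in% names(rq_tbl)))
  rq_tbl |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(d, key) {
      fit <- log2_rq_test(d$rq, alpha = alpha)
      tibble::tibble(
        n = fit$n, mean_log2_rq = fit$mean_log2_rq, rq = fit$estimate_rq,
        statistic = fit$statistic, p_value = fit$p_value,
        significant = fit$significant, direction = fit$direction,
        degenerate_variance = fit$degenerate_variance
      )
    }) |>
    dplyr::ungroup()
}

#' ChIP-qPCR percent input
#'
#' Computes ChIP enrichment as percent of input chromatin. The input Ct
#' is first adjusted for the input dilution factor `DF` (e.g. a 10%
#' input aliquot has `DF = 10`): `Ct* = ct_input - log2(DF)`. Percent
#' input is then `2^-(ct_ip - Ct*) x 100`. Equal IP and adjusted-input
#' Ct gives 100%; each extra IP cycle halves the value.
#'
#' @param chip Tibble with columns `locus`, `ct_ip`, `ct_input` and
#'   either `input_fraction` (e.g. 0.10) or `df` (dilution factor,
#'   `>= 1`); or a numeric vector of `ct_ip` with `ct_input` and `df`
#'   supplied as the further arguments.
#' @param ct_input,df Used when `chip` is numeric.
#' @return For a tibble input: the tibble plus a `percent_input` column.
#'   For numeric input: the numeric percent-input values.
#' @examples
#' percent_input(26, ct_input = 25, df = 10)  # ~5.0
#' @export
percent_input <- function(chip, ct_input = NULL, df = NULL) {
  if (is.numeric(chip)) {
    return(percent_input_value(chip, ct_input, df))
  }
  stopifnot(is.data.frame(chip),
            all(c("ct_ip", "ct_input") %in% names(chip)))
  df_col <- if ("df" %in% names(chip)) chip$df
    else if ("input_fraction" %in% names(chip)) 1 / chip$input_fraction
    else stop("chip table needs `df` or `input_fraction`", call. = FALSE)
  dplyr::mutate(chip,
                percent_input = percent_input_value(.data$ct_ip,
                                                    .data$ct_input, df_col))
}

percent_input_value <- function(ct_ip, ct_input, df) {
  if (any(!is.finite(df)) || any(df < 1)) {
    stop("dilution factor must be >= 1", call. = FALSE)
  }
  adjusted_input <- ct_input - log2(df)
  2^(-(ct_ip - adjusted_input)) * 100
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()] with
#' `method = "BH"`), returned in input order; the usual significance
#' gate is adjusted p of 0.05 or less.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

REGULATION_CLASSES <- c("up_2to5", "up_gt5", "down_2to5", "down_gt5",
                        "unchanged", "not_significant")

#' Classify regulation by fold change and FDR significance
#'
#' Genes failing the significance gate (adjusted p above `alpha`) are
#' `not_significant`. Significant genes are binned on the linear fold
#' magnitude `2^|log2fc|`: below 2 `unchanged`, in `[2, 5)` `*_2to5`,
#' at or above 5 `*_gt5`; the sign of `log2fc` sets up/down. Bins are
#' closed on the left, so a 2-fold change lands in `*_2to5` and a 5-fold
#' change in `*_gt5`.
#'
#' @param log2fc Numeric log2 fold changes (finite).
#' @param adjusted_p FDR-adjusted p-values.
#' @param alpha Significance gate (default 0.05; genes with adjusted p
#'   at or below `alpha` count as significant).
#' @return Character vector of classes among `up_2to5`, `up_gt5`,
#'   `down_2to5`, `down_gt5`, `unchanged`, `not_significant`.
#' @examples
#' classify_regulation(-log2(3), 0.01)  # "down_2to5"
#' @export
classify_regulation <- function(log2fc, adjusted_p, alpha = 0.05) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite", call. = FALSE)
  # bin on the log2 scale so the closed-left edges at 2- and 5-fold are
  # hit exactly (2^log2(5) need not round-trip to 5 in floating point)
  lf <- abs(log2fc)
  dir <- ifelse(log2fc >= 0, "up", "down")
  dplyr::case_when(
    adjusted_p > alpha ~ "not_significant",
    lf < 1 ~ "unchanged",
    lf < log2(5) ~ paste0(dir, "_2to5"),
    TRUE ~ paste0(dir, "_gt5")
  )
}

#' Classify a differential-expression table
#'
#' Applies [bh_fdr()] to the raw p-values (unless the table already
#' carries an `fdr_adjusted_p` column) and [classify_regulation()] to
#' every gene.
#'
#' @param expression Tibble with columns `gene`, `log2fc`, `p_value`
#'   (optionally `fdr_adjusted_p`); [read_expression_table()] produces
#'   this layout.
#' @param alpha Significance gate.
#' @return The tibble plus `fdr_adjusted_p` and `regulation_class`
#'   columns.
#' @export
classify_expression <- function(expression, alpha = 0.05) {
  stopifnot(is.data.frame(expression),
            all(c("gene", "log2fc") %in% names(expression)))
  if (!"fdr_adjusted_p" %in% names(expression)) {
    if (!"p_value" %in% names(expression)) {
      stop("expression table needs `p_value` or `fdr_adjusted_p`", call. = FALSE)
    }
    expression$fdr_adjusted_p <- bh_fdr(expression$p_value)
  }
  dplyr::mutate(expression,
                regulation_class = classify_regulation(.data$log2fc,
                                                       .data$fdr_adjusted_p,
                                                       alpha))
}

#' Join scan candidates with expression classes
#'
#' Full join of a candidate gene list and a classified expression table
#' on normalised (trimmed, upper-cased) symbols; rows present on only
#' one side are flagged rather than dropped.
#'
#' @param expression Classified expression tibble (from
#'   [classify_expression()]).
#' @param candidates Character vector of candidate gene symbols.
#' @return Tibble with one row per gene in the union: `gene`,
#'   `candidate` (logical), `regulation_class` (`NA` when the gene has
#'   no expression row), `in_expression` (logical).
#' @export
integrate_candidates <- function(expression, candidates) {
  stopifnot(is.data.frame(expression),
            all(c("gene", "regulation_class") %in% names(expression)))
  expr <- dplyr::transmute(expression,
                           gene = toupper(trimws(.data$gene)),
                           regulation_class = .data$regulation_class,
                           in_expression = TRUE)
  cand <- tibble::tibble(gene = unique(toupper(trimws(candidates))),
                         candidate = TRUE)
  dplyr::full_join(expr, cand, by = "gene") |>
    dplyr::mutate(candidate = !is.na(.data$candidate),
                  in_expression = !is.na(.data$in_expression)) |>
    dplyr::arrange(.data$gene)
}

#' Read quantitation input tables
#'
#' TSV readers for the three quantitation inputs. The qPCR table has
#' columns `gene`, `replicate`, `condition`, `ct_target`,
#' `ct_reference`, `e_target`, `e_reference`; the ChIP table `locus`,
#' `ct_ip`, `ct_input`, `input_fraction`; the expression table `gene`,
#' `log2fc`, `p_value` (a signed linear `fold_change` column is accepted
#' instead of `log2fc` and converted).
#'
#' @param path TSV file with a header row.
#' @return A tibble in the layout the corresponding computation expects.
#' @export
read_qpcr_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), replicate = readr::col_character(),
    condition = readr::col_character(), .default = readr::col_double()
  ))
}

#' @rdname read_qpcr_table
#' @export
read_chip_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    locus = readr::col_character(), .default = readr::col_double()
  ))
}

#' @rdname read_qpcr_table
#' @export
read_expression_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ))
  if (!"log2fc" %in% names(tbl)) {
    if (!"fold_change" %in% names(tbl)) {
      stop("expression table needs `log2fc` or signed `fold_change`",
           call. = FALSE)
    }
    fc <- tbl$fold_change
    if (any(!is.finite(fc)) || any(abs(fc) < 1)) {
      stop("signed fold changes must have magnitude >= 1", call. = FALSE)
    }
    tbl$log2fc <- sign(fc) * log2(abs(fc))
  }
  tbl
}
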