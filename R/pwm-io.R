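#' Read motif matrices from JASPAR or TRANSFAC text files
#'
#' `read_jaspar()` parses the JASPAR text layout: a `>name` header line
#' followed by four rows `A [ 3 10 0 ... ]` (the brackets are optional, as
#' in older JASPAR flat files). `read_transfac()` parses the TRANSFAC
#' layout: a `PO` (or `P0`) header naming the base columns `A C G T`,
#' numbered rows `01 .. NN` with four numbers each, terminated by `//` or
#' end of file; an `ID`/`NA` line, when present, names the motif.
#'
#' Values are stored as counts unless every position already sums to 1
#' (within 1e-6), in which case the matrix is tagged as frequencies.
#'
#' @param path Path to the motif file.
#' @return A [pwm] object.
#' @export
read_jaspar <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty JASPAR file: ", path, call. = FALSE)
  name <- "motif"
  if (startsWith(lines[1], ">")) {
    name <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) < 4L) {
    stop("JASPAR matrix needs four base rows", call. = FALSE)
  }
  rows <- lapply(lines[1:4], function(l) {
    m <- regmatches(l, regexec("^\\s*([ACGT])\\s*\\[?([^]]*)\\]?\\s*$", l))[[1]]
    if (length(m) != 3L) stop("malformed JASPAR row: ", l, call. = FALSE)
    vals <- as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]])
    if (anyNA(vals)) stop("non-numeric value in JASPAR row: ", l, call. = FALSE)
    list(base = m[2], values = vals)
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  if (!setequal(bases, DNA_BASES)) {
    stop("JASPAR matrix must have one row per base A, C, G, T", call. = FALSE)
  }
  lens <- lengths(lapply(rows, `[[`, "values"))
  if (length(unique(lens)) != 1L) {
    stop("JASPAR base rows have unequal lengths", call. = FALSE)
  }
  mat <- do.call(cbind, lapply(rows, `[[`, "values"))
  colnames(mat) <- bases
  pwm(mat[, DNA_BASES, drop = FALSE], kind = detect_matrix_kind(mat),
      name = name, source_format = "jaspar")
}

#' @rdname read_jaspar
#' @export
read_transfac <- function(path) {
  lines <- readr::read_lines(path)
  name <- "motif"
  id_line <- grep("^(ID|NA)\\s+", lines, value = TRUE)
  if (length(id_line) > 0L) {
    name <- trimws(sub("^(ID|NA)\\s+", "", id_line[1]))
  }
  po <- grep("^P[O0]\\b", lines)
  if (length(po) != 1L) {
    stop("TRANSFAC matrix needs exactly one PO header line", call. = FALSE)
  }
  header <- strsplit(trimws(lines[po]), "\\s+")[[1]][-1]
  if (!setequal(header, DNA_BASES)) {
    stop("TRANSFAC PO header must name columns A C G T", call. = FALSE)
  }
  body <- lines[-seq_len(po)]
  rows <- list()
  for (l in body) {
    l <- trimws(l)
    if (l == "" ) next
    if (startsWith(l, "//") || grepl("^XX", l)) break
    fields <- strsplit(l, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", fields[1])) next  # trailing annotation lines
    if (length(fields) < 5L) {
      stop("malformed TRANSFAC position row: ", l, call. = FALSE)
    }
    vals <- as.numeric(fields[2:5])
    if (anyNA(vals)) stop("non-numeric TRANSFAC row: ", l, call. = FALSE)
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("TRANSFAC matrix has no position rows", call. = FALSE)
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  mat <- mat[, DNA_BASES, drop = FALSE]
  pwm(mat, kind = detect_matrix_kind(mat), name = name,
      source_format = "transfac")
}

detect_matrix_kind <- function(mat) {
  if (all(abs(rowSums(matrix(mat, ncol = 4)) - 1) < 1e-6)) "frequency" else "counts"
}

#' Read/write the normalised internal matrix TSV
#'
#' The internal exchange format is a TSV with columns `position`, `A`,
#' `C`, `G`, `T`, one row per motif position.
#'
#' @param x A [pwm] object.
#' @param path File path.
#' @param name Motif name to attach on read.
#' @return `read_pwm_tsv()` returns a [pwm]; `write_pwm_tsv()` returns
#'   `path` invisibly.
#' @export
write_pwm_tsv <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  tbl <- tibble::as_tibble(x$values)
  tbl <- dplyr::mutate(tbl, position = dplyr::row_number(), .before = 1)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_pwm_tsv
#' @export
read_pwm_tsv <- function(path, name = "motif") {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()))
  need <- c("position", DNA_BASES)
  if (!all(need %in% names(tbl))) {
    stop("matrix TSV must have columns position, A, C, G, T", call. = FALSE)
  }
  mat <- as.matrix(tbl[order(tbl$position), DNA_BASES])
  pwm(mat, kind = detect_matrix_kind(mat), name = name, source_format = "inline")
}

#' Read a motif matrix, guessing the format from content
#'
#' Dispatches to [read_jaspar()], [read_transfac()] or [read_pwm_tsv()]
#' based on the first non-blank line (`>` header, `PO`/`ID` line, or TSV
#' header).
#'
#' @param path Path to a motif file.
#' @param format One of `"auto"`, `"jaspar"`, `"transfac"`, `"tsv"`.
#' @return A [pwm] object.
#' @export
read_matrix <- function(path, format = c("auto", "jaspar", "transfac", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readr::read_lines(path, n_max = 10)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && startsWith(first[1], ">")) "jaspar"
      else if (any(grepl("^(P[O0]|ID|NA)\\b", first))) "transfac"
      else if (length(first) && grepl("^position\t", first[1])) "tsv"
      else "jaspar"
  }
  switch(format,
    jaspar = read_jaspar(path),
    transfac = read_transfac(path),
    tsv = read_pwm_tsv(path)
  )
}
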