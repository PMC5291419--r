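#' Read and write FASTA sequence sets
#'
#' `read_fasta()` loads a (possibly line-wrapped) FASTA file through
#' [Biostrings::readDNAStringSet()] into a tibble; bases are upper-cased.
#' `write_fasta()` writes it back wrapped at 60 columns, so a read/write
#' round trip preserves names and sequences exactly.
#'
#' @param path FASTA file path.
#' @param records Tibble with character columns `name` and `sequence`.
#' @return `read_fasta()` returns a tibble with columns `name`,
#'   `sequence`; duplicate names are an error. `write_fasta()` returns
#'   `path` invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  nm <- names(set)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(name = nm, sequence = unname(toupper(as.character(set))))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("name", "sequence") %in% names(records)))
  set <- Biostrings::DNAStringSet(toupper(records$sequence))
  names(set) <- records$name
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 60L)
  invisible(path)
}

#' Read TSS records from BED6 or GFF3
#'
#' Both readers return transcription start sites in 0-based genomic
#' coordinates. For BED6 (0-based half-open) the TSS is `start` on the
#' plus strand and `end - 1` on the minus strand. For GFF3 gene features
#' (1-based inclusive) it is `start - 1` on plus and `end - 1` on minus,
#' after conversion to 0-based. GFF3 parsing goes through
#' [rtracklayer::import()].
#'
#' @param path Annotation file path.
#' @param feature_type GFF3 feature types to keep (default `"gene"`; use
#'   `NULL` to keep everything).
#' @return Tibble with columns `chrom`, `tss` (0-based), `strand`,
#'   `gene_id`, `gene_symbol`.
#' @export
read_tss_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- which(nzchar(trimws(lines)) &
                  !startsWith(lines, "#") &
                  !startsWith(lines, "track") &
                  !startsWith(lines, "browser"))
  recs <- purrr::map(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 6L) {
      stop(sprintf("%s line %d: BED6 needs 6 tab-separated fields, found %d",
                   path, i, length(fields)), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end) || start < 0 || end < start) {
      stop(sprintf("%s line %d: invalid BED interval '%s'..'%s'",
                   path, i, fields[2], fields[3]), call. = FALSE)
    }
    strand <- fields[6]
    if (!strand %in% c("+", "-")) {
      stop(sprintf("%s line %d: strand must be '+' or '-', found '%s'",
                   path, i, strand), call. = FALSE)
    }
    tibble::tibble(
      chrom = fields[1],
      tss = if (strand == "+") start else end - 1L,
      strand = strand,
      gene_id = fields[4],
      gene_symbol = fields[4]
    )
  })
  if (length(recs) == 0L) {
    return(tibble::tibble(chrom = character(), tss = integer(),
                          strand = character(), gene_id = character(),
                          gene_symbol = character()))
  }
  dplyr::bind_rows(recs)
}

#' @rdname read_tss_bed
#' @export
read_tss_gff3 <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_type)) {
    gr <- gr[as.character(gr$type) %in% feature_type]
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("GFF3 record without an explicit +/- strand", call. = FALSE)
  }
  md <- S4Vectors::mcols(gr)
  pick <- function(cols, fallback) {
    for (cn in cols) {
      if (cn %in% names(md) && !all(is.na(md[[cn]]))) {
        return(as.character(md[[cn]]))
      }
    }
    fallback
  }
  n <- length(gr)
  ids <- pick(c("ID", "gene_id"), paste0("feature_", seq_len(n)))
  symbols <- pick(c("Name", "gene_name", "gene"), ids)
  start0 <- BiocGenerics::start(gr) - 1L  # 1-based inclusive -> 0-based
  end0 <- BiocGenerics::end(gr) - 1L
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    tss = ifelse(strand == "+", start0, end0),
    strand = strand,
    gene_id = ids,
    gene_symbol = symbols
  )
}

#' Extract TSS-anchored promoter windows
#'
#' A promoter window takes `upstream` bases before the TSS and
#' `downstream` bases from the TSS base onward, so the classical
#' -700..+300 window yields exactly 1000 bases with the TSS base at
#' offset `upstream` (0-based) of the output. On the minus strand the
#' genomic interval is mirrored and the sequence reverse-complemented, so
#' output always reads 5'->3' in transcript orientation. Windows running
#' off a contig edge are clipped and flagged `truncated`, never dropped.
#'
#' @param genome Tibble from [read_fasta()] (columns `name`, `sequence`)
#'   or a named character vector of chromosome sequences.
#' @param tss Tibble of TSS records as returned by [read_tss_bed()] /
#'   [read_tss_gff3()]: columns `chrom`, `tss`, `strand`, `gene_id`, and
#'   optionally `gene_symbol`.
#' @param upstream,downstream Window geometry in bases
#'   (`upstream + downstream >= 1`). Defaults 700 and 300.
#' @return Tibble with one row per TSS record: `promoter_id` (gene, TSS
#'   and strand), `gene_id`, `gene_symbol`, `chrom`, `tss`, `strand`,
#'   `start`, `end` (0-based half-open genomic span actually used),
#'   `sequence`, `truncated`, `upstream`, `downstream`.
#' @examples
#' g <- tibble::tibble(name = "chr1", sequence = "AAAACGTTTT")
#' t <- tibble::tibble(chrom = "chr1", tss = 4, strand = "+", gene_id = "g1")
#' extract_promoters(g, t, upstream = 2, downstream = 2)$sequence  # "AACG"
#' @export
extract_promoters <- function(genome, tss, upstream = 700, downstream = 300) {
  if (is.data.frame(genome)) {
    genome <- stats::setNames(genome$sequence, genome$name)
  }
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (is.na(upstream) || is.na(downstream) || upstream < 0 || downstream < 0 ||
      upstream + downstream < 1L) {
    stop("window must satisfy upstream >= 0, downstream >= 0, sum >= 1",
         call. = FALSE)
  }
  if (!"gene_symbol" %in% names(tss)) tss$gene_symbol <- tss$gene_id
  purrr::pmap_dfr(
    tss[, c("chrom", "tss", "strand", "gene_id", "gene_symbol")],
    function(chrom, tss, strand, gene_id, gene_symbol) {
      tss <- as.integer(tss)
      if (!chrom %in% names(genome)) {
        stop("chromosome not in genome: ", chrom, call. = FALSE)
      }
      chrom_seq <- genome[[chrom]]
      n <- nchar(chrom_seq)
      if (strand == "+") {
        s <- tss - upstream; e <- tss + downstream
      } else if (strand == "-") {
        s <- tss - downstream + 1L; e <- tss + upstream + 1L
      } else {
        stop("strand must be '+' or '-', found '", strand, "'", call. = FALSE)
      }
      cs <- max(0L, s); ce <- min(n, e)
      seq <- if (ce > cs) toupper(substr(chrom_seq, cs + 1L, ce)) else ""
      if (strand == "-") seq <- reverse_complement(seq)
      tibble::tibble(
        promoter_id = sprintf("%s@%s:%d:%s", gene_id, chrom, tss, strand),
        gene_id = gene_id, gene_symbol = gene_symbol,
        chrom = chrom, tss = as.integer(tss), strand = strand,
        start = cs, end = ce, sequence = seq,
        truncated = (cs != s) || (ce != e),
        upstream = upstream, downstream = downstream
      )
    }
  )
}

#' Read a curated target table
#'
#' Reads a tab-separated target table whose first five columns are gene
#' symbol, gene name, accession, and two per-species dissimilarity scores
#' (percent); a sixth column, when present, is kept as a free-text
#' annotation. Score cells tolerate decimal commas (`"0,43"` is 0.43) and
#' `"N/A"` for missing; anything else non-numeric is a parse error.
#'
#' @param path TSV path with a header row.
#' @return Tibble with columns `gene_symbol`, `gene_name`, `accession`,
#'   `score_a`, `score_b` (numeric, `NA` where missing) and `annotation`
#'   (character, `NA` when the table has no sixth column).
#' @export
read_target_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tbl) < 5L) {
    stop("target table needs at least 5 tab-separated columns", call. = FALSE)
  }
  out <- tibble::tibble(
    gene_symbol = tbl[[1]],
    gene_name = tbl[[2]],
    accession = tbl[[3]],
    score_a = parse_score(tbl[[4]], names(tbl)[4]),
    score_b = parse_score(tbl[[5]], names(tbl)[5]),
    annotation = if (ncol(tbl) >= 6L) tbl[[6]] else NA_character_
  )
  bad <- stats::na.omit(c(out$score_a, out$score_b))
  if (any(bad < 0 | bad > 100)) {
    stop("dissimilarity scores must lie in [0, 100]", call. = FALSE)
  }
  out
}

parse_score <- function(x, column) {
  x <- trimws(x)
  missing <- is.na(x) | x == "" | toupper(x) == "N/A"
  val <- suppressWarnings(as.numeric(sub(",", ".", x, fixed = TRUE)))
  bad <- !missing & is.na(val)
  if (any(bad)) {
    stop(sprintf("column '%s': cannot parse score cell(s): %s", column,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  val[missing] <- NA_real_
  val
}
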