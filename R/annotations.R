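#' Parse a UCSC refGene-format annotation table
#'
#' Reads a header-less, tab-separated refGene table (plain text or gzip) and
#' returns one transcript record per line. Coordinates follow the UCSC
#' convention: 0-based, half-open `[tx_start, tx_end)`.
#'
#' Only the columns the downstream analysis needs are retained: `name`
#' (transcript id, column 2), `chrom` (3), `strand` (4), `txStart` (5),
#' `txEnd` (6) and `name2` (gene symbol, column 13).
#'
#' @param file Path to a `refGene.txt` or `refGene.txt.gz` file, or a
#'   connection / character vector of lines.
#' @return A data.frame with columns `transcript_id`, `gene_name`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`; one row per input line, duplicates
#'   preserved (collapse with [select_longest_transcripts()]).
#' @seealso [select_longest_transcripts()], [write_refgene()]
#' @export
parse_refgene <- function(file) {
  lines <- if (is.character(file) && length(file) > 1) {
    file
  } else if (is.character(file) && !file.exists(file) && grepl("\t", file)) {
    # a single literal line rather than a path
    file
  } else {
    readLines(if (is.character(file)) gzfile(file) else file)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(
      transcript_id = character(), gene_name = character(),
      chrom = character(), strand = character(),
      tx_start = integer(), tx_end = integer(),
      stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 16L)
  if (length(bad) > 0L) {
    stop_input(
      "refGene parse error: line ", bad[1L], " has ", nf[bad[1L]],
      " tab-separated fields (>= 16 required)"
    )
  }
  get_col <- function(i) vapply(fields, `[[`, character(1), i)
  tx_start <- suppressWarnings(as.integer(get_col(5L)))
  tx_end <- suppressWarnings(as.integer(get_col(6L)))
  bad <- which(is.na(tx_start) | is.na(tx_end))
  if (length(bad) > 0L) {
    stop_input(
      "refGene parse error: non-integer txStart/txEnd on line ", bad[1L]
    )
  }
  strand <- get_col(4L)
  # tolerate the unicode minus some exports carry
  strand[strand == "−"] <- "-"
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop_input(
      "refGene parse error: unknown strand symbol ",
      sQuote(strand[bad[1L]]), " on line ", bad[1L]
    )
  }
  bad <- which(tx_start >= tx_end)
  if (length(bad) > 0L) {
    stop_input("refGene parse error: txStart >= txEnd on line ", bad[1L])
  }
  data.frame(
    transcript_id = get_col(2L),
    gene_name = get_col(13L),
    chrom = get_col(3L),
    strand = strand,
    tx_start = tx_start,
    tx_end = tx_end,
    stringsAsFactors = FALSE
  )
}

#' Collapse transcripts to one longest transcript per gene
#'
#' For each distinct gene symbol, the transcript maximizing
#' `tx_end - tx_start` is kept. Ties are broken by `(chrom, tx_start,
#' transcript_id)` ascending. Genes whose symbol appears on several
#' chromosomes (paralog collisions) are collapsed to the single genome-wide
#' longest transcript, with a warning.
#'
#' @param records Transcript data.frame from [parse_refgene()].
#' @param chroms Optional chromosome whitelist; transcripts on other
#'   chromosomes are dropped before collapsing.
#' @return A gene-model data.frame with columns `gene_name`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `tss` (strand-aware transcription start,
#'   0-based), sorted by `gene_name`.
#' @export
select_longest_transcripts <- function(records, chroms = NULL) {
  if (!is.null(chroms)) {
    records <- records[records$chrom %in% chroms, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop_input("select_longest_transcripts: no transcript records")
  }
  multi <- tapply(records$chrom, records$gene_name,
                  function(x) length(unique(x)) > 1L)
  if (any(multi)) {
    warning(
      "gene symbol(s) on multiple chromosomes collapsed genome-wide: ",
      paste(names(multi)[multi], collapse = ", "),
      call. = FALSE
    )
  }
  len <- records$tx_end - records$tx_start
  ord <- order(records$gene_name, -len, records$chrom, records$tx_start,
               records$transcript_id)
  records <- records[ord, , drop = FALSE]
  keep <- !duplicated(records$gene_name)
  models <- records[keep, c("gene_name", "chrom", "strand",
                            "tx_start", "tx_end"), drop = FALSE]
  models$tss <- tss_of(models)
  rownames(models) <- NULL
  models
}

#' Strand-aware transcription start site
#'
#' The TSS of a plus-strand transcript is `tx_start`; for a minus-strand
#' transcript it is `tx_end - 1`, the last covered base of the half-open
#' interval (0-based coordinates throughout).
#'
#' @param models Data.frame with `strand`, `tx_start`, `tx_end`.
#' @return Integer vector of 0-based TSS positions.
#' @export
tss_of <- function(models) {
  ifelse(models$strand == "+", models$tx_start, models$tx_end - 1L)
}

#' Write gene models (or transcripts) back to refGene dialect
#'
#' Emits the same 16-column, header-less tab-separated dialect
#' [parse_refgene()] reads; unused columns are filled with placeholders so a
#' write/parse round trip reproduces the models exactly.
#'
#' @param models Data.frame with `gene_name`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` and optionally `transcript_id`.
#' @param file Output path (or connection).
#' @export
write_refgene <- function(models, file) {
  tid <- if ("transcript_id" %in% names(models)) {
    models$transcript_id
  } else {
    paste0("TX_", models$gene_name)
  }
  lines <- paste(
    0L, tid, models$chrom, models$strand, models$tx_start, models$tx_end,
    models$tx_start, models$tx_end, 1L,
    paste0(models$tx_start, ","), paste0(models$tx_end, ","),
    0L, models$gene_name, "cmpl", "cmpl", "0,",
    sep = "\t"
  )
  writeLines(lines, file)
  invisible(file)
}

#' Write TSS points as 6-column BED
#'
#' One zero-length-style record per gene: `chrom, tss, tss + 1, gene, 0,
#' strand` (BED is 0-based half-open, so the record covers exactly the TSS
#' base).
#'
#' @inheritParams write_refgene
#' @export
write_tss_bed <- function(models, file) {
  lines <- paste(models$chrom, models$tss, models$tss + 1L,
                 models$gene_name, 0L, models$strand, sep = "\t")
  writeLines(lines, file)
  invisible(file)
}
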