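#' Occupancy window configuration
#'
#' The canonical analysis averages signal in 100-bp bins over a 10-kb window
#' centered at the TSS (5 kb up- and downstream), giving 100 bins per gene.
#'
#' @param window_bp Half-window in bp (default 5000).
#' @param bin_bp Bin width in bp (default 100); `2 * window_bp` must be a
#'   multiple of `bin_bp`.
#' @param orient_strand Flip bins of minus-strand genes so bin 1 is always
#'   5'/upstream of the gene (default `TRUE`).
#' @return A list of class `OccupancyConfig`.
#' @export
occupancy_config <- function(window_bp = 5000, bin_bp = 100,
                             orient_strand = TRUE) {
  stopifnot(window_bp > 0, bin_bp > 0)
  if ((2 * window_bp) %% bin_bp != 0) {
    stop_input("occupancy_config: 2*window_bp must be divisible by bin_bp")
  }
  structure(
    list(window_bp = window_bp, bin_bp = bin_bp,
         orient_strand = isTRUE(orient_strand)),
    class = "OccupancyConfig"
  )
}

#' Bin midpoint offsets of a configuration
#'
#' @param cfg An [occupancy_config()].
#' @return Numeric vector of bin-center offsets relative to the TSS
#'   (-4950 ... +4950 for defaults).
#' @export
bin_offsets <- function(cfg) {
  seq(-cfg$window_bp + cfg$bin_bp / 2, cfg$window_bp - cfg$bin_bp / 2,
      by = cfg$bin_bp)
}

#' Build a TSS-centered occupancy matrix
#'
#' For every gene, the depth-scaled signal is averaged in `bin_bp`-wide bins
#' across `[tss - window_bp, tss + window_bp)`. Rows of minus-strand genes
#' are mirrored (when `orient_strand`) so that bin 1 is the gene's
#' 5'/upstream flank: for a plus-strand gene bin `i` covers
#' `[tss - W + (i-1) b, tss - W + i b)`; for a minus-strand gene the mirror
#' image `[tss + W - i b, tss + W - (i-1) b)`.
#'
#' Bins extending past chromosome position 0 are zero-filled and the gene's
#' `edge_clipped` flag is set. Genes on chromosomes absent from the track get
#' all-zero rows with a warning.
#'
#' @param genes Gene-model data.frame from [select_longest_transcripts()].
#' @param track A depth-scaled [coverage_track()].
#' @param cfg An [occupancy_config()].
#' @return A numeric matrix of class `OccupancyMatrix` (genes x bins,
#'   rownames = gene names) with attributes `offsets` (bin centers) and
#'   `edge_clipped` (logical per gene).
#' @export
build_occupancy_matrix <- function(genes, track, cfg = occupancy_config()) {
  stopifnot(nrow(genes) > 0)
  w <- cfg$window_bp
  b <- cfg$bin_bp
  nbin <- as.integer(2 * w / b)
  n <- nrow(genes)
  mat <- matrix(0, nrow = n, ncol = nbin, dimnames = list(genes$gene_name))
  clipped <- logical(n)
  missing_chr <- setdiff(unique(genes$chrom), names(track$rle))
  if (length(missing_chr) > 0L) {
    warning("chromosome(s) absent from track, rows zero-filled: ",
            paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  i_bins <- seq_len(nbin)
  for (chr in intersect(unique(genes$chrom), names(track$rle))) {
    idx <- which(genes$chrom == chr)
    tss <- genes$tss[idx]
    strand <- genes$strand[idx]
    # bin start offsets relative to TSS, per gene (rows) x bin (cols)
    plus_starts <- -w + (i_bins - 1L) * b
    minus_starts <- w - i_bins * b
    offs <- matrix(plus_starts, nrow = length(idx), ncol = nbin,
                   byrow = TRUE)
    if (cfg$orient_strand) {
      flip <- strand == "-"
      if (any(flip)) {
        offs[flip, ] <- matrix(minus_starts, nrow = sum(flip), ncol = nbin,
                               byrow = TRUE)
      }
    }
    starts <- offs + tss
    ends <- starts + b
    clipped[idx] <- rowSums(starts < 0) > 0
    vals <- mean_signal(track, chr, as.vector(starts), as.vector(ends))
    mat[idx, ] <- matrix(vals, nrow = length(idx), ncol = nbin)
  }
  structure(mat,
            offsets = bin_offsets(cfg),
            edge_clipped = stats::setNames(clipped, genes$gene_name),
            class = c("OccupancyMatrix", class(mat)))
}

#' Write an occupancy matrix as TSV
#'
#' Header row carries the bin midpoint offsets; one row per gene; a final
#' `edge_clipped` column preserves the per-gene flag. Values are written at
#' full double precision so write/read round trips are lossless.
#'
#' @param matrix An `OccupancyMatrix`.
#' @param file Output path or connection.
#' @export
write_occupancy_matrix <- function(matrix, file) {
  offs <- attr(matrix, "offsets")
  clip <- attr(matrix, "edge_clipped")
  header <- paste(c("gene", offs, "edge_clipped"), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], fmt_num(matrix[i, ]),
            as.character(clip[i])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), file)
  invisible(file)
}

#' Read an occupancy matrix TSV written by [write_occupancy_matrix()]
#'
#' @param file Input path or connection.
#' @return An `OccupancyMatrix`.
#' @export
read_occupancy_matrix <- function(file) {
  lines <- readLines(if (is.character(file)) gzfile(file) else file)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    stop_input("occupancy matrix format error: ragged rows (",
               paste(unique(nf), collapse = "/"), " fields)")
  }
  header <- fields[[1L]]
  offs <- as.numeric(header[-c(1L, length(header))])
  body <- fields[-1L]
  genes <- vapply(body, `[[`, character(1), 1L)
  clip <- as.logical(vapply(body, `[[`, character(1), length(header)))
  vals <- t(vapply(body, function(f) {
    as.numeric(f[-c(1L, length(f))])
  }, numeric(length(offs))))
  rownames(vals) <- genes
  structure(vals,
            offsets = offs,
            edge_clipped = stats::setNames(clip, genes),
            class = c("OccupancyMatrix", class(vals)))
}

#' @export
`[.OccupancyMatrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- unclass(x)
  offs <- attr(x, "offsets")
  clip <- attr(x, "edge_clipped")
  attr(out, "offsets") <- NULL
  attr(out, "edge_clipped") <- NULL
  if (missing(i)) i <- seq_len(nrow(out))
  if (missing(j)) j <- seq_len(ncol(out))
  out <- out[i, j, drop = drop]
  if (!is.matrix(out)) return(out)
  offs <- offs[j]
  structure(out,
            offsets = offs,
            edge_clipped = clip[rownames(out)],
            class = c("OccupancyMatrix", "matrix", "array"))
}

#' @export
print.OccupancyMatrix <- function(x, ...) {
  cat("OccupancyMatrix:", nrow(x), "genes x", ncol(x), "bins; offsets",
      min(attr(x, "offsets")), "..", max(attr(x, "offsets")), "\n")
  invisible(x)
}
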