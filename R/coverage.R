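#' Coverage tracks
#'
#' A `CoverageTrack` is a piecewise-constant, per-chromosome signal, as
#' produced by ChIP-seq tag pileup tools, with implicit value 0 wherever no
#' interval covers a base. Intervals are stored 0-based half-open and, per
#' chromosome, sorted and non-overlapping. `scale_factor` records the depth
#' scaling already applied (1 for a raw pileup).
#'
#' @param intervals Data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open, `value >= 0`).
#' @param scale_factor Multiplier already applied to `value`.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(intervals, scale_factor = 1) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  iv <- intervals[, c("chrom", "start", "end", "value")]
  iv$start <- as.numeric(iv$start)
  iv$end <- as.numeric(iv$end)
  iv$value <- as.numeric(iv$value)
  if (any(!is.finite(iv$value)) || any(iv$value < 0)) {
    stop_input("coverage format error: negative or non-finite value")
  }
  if (any(iv$start >= iv$end)) {
    stop_input("coverage format error: interval with start >= end")
  }
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  same <- iv$chrom[-1L] == iv$chrom[-nrow(iv)]
  if (nrow(iv) > 1L) {
    bad <- which(same & iv$start[-1L] < iv$end[-nrow(iv)])
    if (length(bad) > 0L) {
      i <- bad[1L]
      stop_input(
        "coverage format error: overlapping intervals on ", iv$chrom[i],
        ": [", iv$start[i], ",", iv$end[i], ") and [",
        iv$start[i + 1L], ",", iv$end[i + 1L], ")"
      )
    }
  }
  rownames(iv) <- NULL
  structure(
    list(
      intervals = iv,
      rle = .track_rle(iv),
      scale_factor = as.numeric(scale_factor)
    ),
    class = "CoverageTrack"
  )
}

# One S4Vectors::Rle per chromosome over [1, max end]; implicit zeros kept as
# literal zero runs so Views arithmetic sees them.
.track_rle <- function(iv) {
  out <- list()
  for (chr in unique(iv$chrom)) {
    sub <- iv[iv$chrom == chr, , drop = FALSE]
    # gap before each interval (1-based): previous end .. start
    gaps <- sub$start - c(0, sub$end[-nrow(sub)])
    vals <- as.vector(rbind(0, sub$value))
    lens <- as.vector(rbind(gaps, sub$end - sub$start))
    keep <- lens > 0
    out[[chr]] <- S4Vectors::Rle(vals[keep], lens[keep])
  }
  out
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", nrow(x$intervals), "intervals on",
      length(x$rle), "chromosome(s); scale_factor =",
      format(x$scale_factor), "\n")
  invisible(x)
}

#' Read a bedGraph coverage pileup
#'
#' Accepts 4-column bedGraph (`chrom start end value`, 0-based half-open).
#' `track`, `browser` and `#` comment lines are skipped. Intervals may arrive
#' unsorted; overlapping intervals or negative values are format errors.
#'
#' @param file Path or connection.
#' @return A [coverage_track()] with `scale_factor = 1`.
#' @export
read_bedgraph <- function(file) {
  lines <- readLines(if (is.character(file)) gzfile(file) else file)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(coverage_track(data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      value = numeric()
    )))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop_input("bedGraph format error: line ", which(nf < 4L)[1L],
               " has fewer than 4 fields")
  }
  df <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start = as.numeric(vapply(fields, `[[`, character(1), 2L)),
    end = as.numeric(vapply(fields, `[[`, character(1), 3L)),
    value = as.numeric(vapply(fields, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value)) {
    stop_input("bedGraph format error: non-numeric coordinate or value")
  }
  coverage_track(df)
}

#' Write a track as canonical bedGraph
#'
#' Zero-value intervals are dropped (implicit-zero convention) and adjacent
#' intervals with equal value are merged, so read/write round trips are
#' stable on canonical tracks.
#'
#' @param track A `CoverageTrack`.
#' @param file Output path or connection.
#' @export
write_bedgraph <- function(track, file) {
  iv <- track$intervals
  iv <- iv[iv$value > 0, , drop = FALSE]
  if (nrow(iv) > 1L) {
    # merge runs of touching, equal-valued intervals
    new_run <- c(TRUE, !(iv$chrom[-1L] == iv$chrom[-nrow(iv)] &
                           iv$start[-1L] == iv$end[-nrow(iv)] &
                           iv$value[-1L] == iv$value[-nrow(iv)]))
    last_of_run <- c(which(new_run)[-1L] - 1L, nrow(iv))
    iv <- data.frame(
      chrom = iv$chrom[new_run],
      start = iv$start[new_run],
      end = iv$end[last_of_run],
      value = iv$value[new_run]
    )
  }
  writeLines(
    paste(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
          format(iv$end, scientific = FALSE, trim = TRUE),
          fmt_num(iv$value), sep = "\t"),
    file
  )
  invisible(file)
}

#' Scale a pileup to one million mappable reads
#'
#' Multiplies every interval value by `1e6 / mappable_reads`, the standard
#' depth normalization that puts libraries of different sequencing depth on
#' a common scale. `scale_factor` is updated multiplicatively.
#'
#' @param track A `CoverageTrack`.
#' @param mappable_reads Positive library size (mappable read count).
#' @return The scaled `CoverageTrack`.
#' @export
scale_to_million <- function(track, mappable_reads) {
  if (!is.numeric(mappable_reads) || length(mappable_reads) != 1L ||
      !is.finite(mappable_reads) || mappable_reads <= 0) {
    stop_input("scale_to_million: mappable_reads must be a positive number")
  }
  f <- 1e6 / mappable_reads
  iv <- track$intervals
  iv$value <- iv$value * f
  coverage_track(iv, scale_factor = track$scale_factor * f)
}

#' Mean signal over genomic intervals
#'
#' Average signal per base over `[start, end)` (0-based half-open), counting
#' uncovered bases — including bases beyond the last interval or on a
#' chromosome absent from the track — as 0.
#'
#' @param track A `CoverageTrack`.
#' @param chrom Chromosome name (scalar).
#' @param start,end Numeric vectors of query bounds, `start < end`.
#' @return Numeric vector of per-base means, one per query.
#' @export
mean_signal <- function(track, chrom, start, end) {
  if (any(start >= end)) {
    stop_input("mean_signal: start must be < end")
  }
  n <- length(start)
  stopifnot(length(end) == n, length(chrom) == 1L)
  rle <- track$rle[[chrom]]
  if (is.null(rle)) {
    return(numeric(n))
  }
  len <- length(rle)
  # clip to the represented range; out-of-range bases contribute 0
  s1 <- pmax(start + 1, 1)   # to 1-based inclusive
  e1 <- pmin(end, len)
  sums <- numeric(n)
  ok <- s1 <= e1 & s1 <= len & e1 >= 1
  if (any(ok)) {
    v <- IRanges::Views(rle, start = s1[ok], end = e1[ok])
    sums[ok] <- IRanges::viewSums(v)
  }
  sums / (end - start)
}

#' Genome-binned means of a track
#'
#' @param track A `CoverageTrack`.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param bin_bp Bin width in bp.
#' @return Numeric vector concatenating per-chromosome bin means, in
#'   `names(chrom_sizes)` order.
#' @export
binned_means <- function(track, chrom_sizes, bin_bp = 1000) {
  stopifnot(bin_bp > 0, length(chrom_sizes) > 0, !is.null(names(chrom_sizes)))
  out <- lapply(names(chrom_sizes), function(chr) {
    size <- chrom_sizes[[chr]]
    starts <- seq(0, size - 1, by = bin_bp)
    ends <- pmin(starts + bin_bp, size)
    mean_signal(track, chr, starts, ends)
  })
  unlist(out, use.names = FALSE)
}

#' Genome-wide track similarity
#'
#' Pearson correlation of two tracks' binned mean-signal vectors over all
#' bins of all chromosomes — a scalar summary of whether two pileups (e.g.
#' two genotypes' EZH2 maps) show the same genomic distribution of signal.
#'
#' @param track_a,track_b Depth-scaled `CoverageTrack` objects.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param bin_bp Bin width in bp (default 1000).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
track_similarity <- function(track_a, track_b, chrom_sizes, bin_bp = 1000) {
  a <- binned_means(track_a, chrom_sizes, bin_bp)
  b <- binned_means(track_b, chrom_sizes, bin_bp)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_input("track_similarity: a binned signal vector is constant; ",
               "correlation undefined")
  }
  stats::cor(a, b)
}
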