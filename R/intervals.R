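#' Genomic intervals
#'
#' Construct a validated table of genomic intervals. All coordinates in the
#' package are 0-based, half-open (the BED convention): an interval covers
#' bases `start .. end - 1`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open coordinates;
#'   `0 <= start < end` is required.
#' @param ... further equal-length columns (e.g. `name`, `score`) carried
#'   along unchecked.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (and any extra
#'   columns), sorted by `(chrom, start, end)`.
#' @examples
#' gintervals("chr1", c(0L, 500L), c(200L, 900L))
#' @export
gintervals <- function(chrom, start, end, ...) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  ...,
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("invalid %s(s) at row(s) %s: need 0 <= start < end",
                 what, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  invisible(x)
}

#' Merge genomic intervals separated by at most a maximum gap
#'
#' Reimplements the `bedtools merge -d` stitching convention: two intervals on
#' the same chromosome are merged when the gap between them
#' (`start_next - end_prev`) is at most `max_gap`; overlapping or book-ended
#' intervals (gap <= 0) always merge.
#'
#' @param intervals interval `data.frame` (see [gintervals()]); need not be
#'   sorted or disjoint.
#' @param max_gap non-negative integer, the largest gap (bp) closed by
#'   merging. `max_gap = 1` reproduces `mergeBed -d 1`.
#' @return Sorted, pairwise non-overlapping intervals, any two consecutive
#'   ones on a chromosome separated by more than `max_gap` bp.
#' @examples
#' merge_intervals(gintervals("chr1", c(0L, 101L), c(100L, 200L)), max_gap = 1L)
#' @export
merge_intervals <- function(intervals, max_gap = 0L) {
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative integer")
  validate_intervals(intervals)
  if (nrow(intervals) == 0L)
    return(intervals[, c("chrom", "start", "end")])
  x <- intervals[order(intervals$chrom, intervals$start, intervals$end), , drop = FALSE]
  new_chrom <- c(TRUE, x$chrom[-1L] != x$chrom[-nrow(x)])
  # running maximum of end within chromosome
  hi <- x$end
  for (i in seq_len(nrow(x))[-1L]) {
    if (!new_chrom[i] && hi[i - 1L] > hi[i]) hi[i] <- hi[i - 1L]
    if (new_chrom[i]) hi[i] <- x$end[i]
  }
  gap_prev <- c(Inf, x$start[-1L] - hi[-nrow(x)])
  grp <- cumsum(new_chrom | gap_prev > max_gap)
  first <- !duplicated(grp)
  data.frame(
    chrom = x$chrom[first],
    start = x$start[first],
    end = as.integer(unname(tapply(x$end, grp, max))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bidirectional overlap test for two intervals
#'
#' Two intervals overlap bidirectionally at fraction `min_fraction` when the
#' overlap length is at least that fraction of the length of *each* interval.
#' This is the reciprocal-overlap criterion used to call enhancers shared
#' between two conditions.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b vectors describing the
#'   two interval sets, recycled to common length.
#' @param min_fraction fraction in (0, 1]; default 0.25.
#' @return Logical vector; `FALSE` for pairs on different chromosomes.
#' @export
bidirectional_overlap <- function(chrom_a, start_a, end_a,
                                  chrom_b, start_b, end_b,
                                  min_fraction = 0.25) {
  if (any(min_fraction <= 0 | min_fraction > 1))
    stop("min_fraction must be in (0, 1]")
  ov <- pmin(end_a, end_b) - pmax(start_a, start_b)
  ok <- chrom_a == chrom_b &
    ov >= min_fraction * (end_a - start_a) &
    ov >= min_fraction * (end_b - start_b)
  ok & ov > 0
}

#' Distance from a point to an interval
#'
#' Zero when the position falls inside the half-open interval, otherwise the
#' distance to the nearest *covered* base (i.e. `start` or `end - 1`).
#' Positions on a different chromosome get `Inf`.
#'
#' @param chrom,start,end interval (vectors recycled against `position`).
#' @param position base position(s), 0-based.
#' @param pos_chrom chromosome of the position(s); defaults to `chrom`
#'   (same-chromosome distance).
#' @return Numeric vector of distances in bp (`Inf` across chromosomes).
#' @examples
#' min_distance("chr1", 100L, 200L, 250L) # 51: nearest covered base is 199
#' @export
min_distance <- function(chrom, start, end, position, pos_chrom = chrom) {
  if (any(position < 0)) stop("position must be >= 0")
  d <- pmax(start - position, position - (end - 1L), 0L)
  d <- as.numeric(d)
  d[pos_chrom != chrom] <- Inf
  d
}

interval_midpoint <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

# index pairs (i, j) such that a[i] and b[j] overlap by >= min_overlap bp.
# a and b are interval data.frames; neither needs to be internally disjoint.
overlap_pairs <- function(a, b, min_overlap = 1L) {
  out_i <- integer(0); out_j <- integer(0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    jb <- which(b$chrom == ch)
    bo <- jb[order(b$start[jb], b$end[jb])]
    bs <- b$start[bo]; be <- b$end[bo]
    cm <- cummax(be)
    for (i in ia) {
      # candidates: first j with cummax(end) > a_start, up to start < a_end
      lo <- findInterval(a$start[i] + min_overlap - 1L, cm) + 1L
      if (lo > length(bo)) next
      hi <- findInterval(a$end[i] - min_overlap, bs)
      if (hi < lo) next
      cand <- lo:hi
      ok <- pmin(a$end[i], be[cand]) - pmax(a$start[i], bs[cand]) >= min_overlap
      if (any(ok)) {
        out_i <- c(out_i, rep.int(i, sum(ok)))
        out_j <- c(out_j, bo[cand[ok]])
      }
    }
  }
  data.frame(i = out_i, j = out_j)
}
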