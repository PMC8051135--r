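#' Call enhancers from a chromatin-state segmentation
#'
#' Extracts the segments whose state is an enhancer state and stitches
#' adjacent ones together with [merge_intervals()] (the
#' `mergeBed -d 1` convention), then flags stretch enhancers: merged
#' intervals strictly longer than `stretch_min_bp` (> 3 kb by default).
#'
#' @param seg a [segmentation()].
#' @param enhancer_states integer set of enhancer states; default `c(2, 3)`.
#' @param max_gap largest gap (bp) closed when stitching; default 1.
#' @param stretch_min_bp strict length threshold for the stretch flag;
#'   default 3000 ("larger than 3 kb").
#' @param label label stored on the result (e.g. the condition).
#' @return A `data.frame` of class `"enhancer_set"` with columns `chrom`,
#'   `start`, `end`, `length`, `is_stretch`, `source_states` (comma-joined
#'   states observed inside each enhancer), and attributes recording the
#'   parameters used.
#' @examples
#' seg <- segmentation(data.frame(chrom = "chr1",
#'                                start = c(0L, 200L, 400L),
#'                                end = c(200L, 400L, 600L),
#'                                state = c(2L, 3L, 1L)))
#' call_enhancers(seg)
#' @export
call_enhancers <- function(seg, enhancer_states = c(2L, 3L), max_gap = 1L,
                           stretch_min_bp = 3000L, label = "enhancers") {
  stopifnot(inherits(seg, "segmentation"))
  if (!all(enhancer_states %in% seq_len(seg$state_count)))
    stop("enhancer_states must be within 1..state_count")
  s <- seg$segments[seg$segments$state %in% enhancer_states, , drop = FALSE]
  merged <- merge_intervals(s[, c("chrom", "start", "end")], max_gap = max_gap)
  src <- character(nrow(merged))
  if (nrow(merged)) {
    pr <- overlap_pairs(merged, s)
    sp <- split(s$state[pr$j], pr$i)
    for (k in names(sp))
      src[as.integer(k)] <- paste(sort(unique(sp[[k]])), collapse = ",")
  }
  out <- data.frame(merged,
                    length = merged$end - merged$start,
                    is_stretch = (merged$end - merged$start) > stretch_min_bp,
                    source_states = src,
                    stringsAsFactors = FALSE)
  structure(out, label = label, enhancer_states = enhancer_states,
            max_gap = max_gap, stretch_min_bp = stretch_min_bp,
            class = c("enhancer_set", "data.frame"))
}

#' Shared and unique enhancers between two conditions
#'
#' An enhancer in one set is "shared" when at least one enhancer in the other
#' set overlaps it bidirectionally at `min_fraction` (default: at least 25%
#' reciprocal overlap). Overlaps are not summed across partners. The
#' Venn-style headline is also reported as connected components of the
#' sharing relation that contain members of both sets.
#'
#' @param set_a,set_b [call_enhancers()] results (internally non-overlapping).
#' @param min_fraction reciprocal-overlap fraction in (0, 1].
#' @return A list of class `"enhancer_sharing"`: per-set logical vectors
#'   `shared_a`, `shared_b`; counts `n_a`, `n_b`, `n_shared_a`, `n_unique_a`,
#'   `n_shared_b`, `n_unique_b`; `fraction_shared_union`
#'   (`(n_shared_a + n_shared_b) / (n_a + n_b)`); and Venn component counts
#'   `venn_shared`, `venn_unique_a`, `venn_unique_b`.
#' @export
shared_enhancers <- function(set_a, set_b, min_fraction = 0.25) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  pr <- overlap_pairs(set_a, set_b)
  ok <- bidirectional_overlap(set_a$chrom[pr$i], set_a$start[pr$i], set_a$end[pr$i],
                              set_b$chrom[pr$j], set_b$start[pr$j], set_b$end[pr$j],
                              min_fraction)
  pi <- pr$i[ok]; pj <- pr$j[ok]
  shared_a <- seq_len(nrow(set_a)) %in% pi
  shared_b <- seq_len(nrow(set_b)) %in% pj
  # connected components over A (1..nA) and B (nA+1..nA+nB) under the relation
  parent <- seq_len(nrow(set_a) + nrow(set_b))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(pi)) {
    ra <- find(pi[k]); rb <- find(nrow(set_a) + pj[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(parent), find, 1L)
  is_a <- seq_along(parent) <= nrow(set_a)
  comp_has_a <- tapply(is_a, roots, any)
  comp_has_b <- tapply(!is_a, roots, any)
  structure(list(
    shared_a = shared_a, shared_b = shared_b,
    n_a = nrow(set_a), n_b = nrow(set_b),
    n_shared_a = sum(shared_a), n_unique_a = sum(!shared_a),
    n_shared_b = sum(shared_b), n_unique_b = sum(!shared_b),
    fraction_shared_union = (sum(shared_a) + sum(shared_b)) /
      max(1L, nrow(set_a) + nrow(set_b)),
    venn_shared = sum(comp_has_a & comp_has_b),
    venn_unique_a = sum(comp_has_a & !comp_has_b),
    venn_unique_b = sum(comp_has_a == FALSE & comp_has_b),
    min_fraction = min_fraction), class = "enhancer_sharing")
}

#' @export
print.enhancer_sharing <- function(x, ...) {
  cat(sprintf("Enhancer sharing (reciprocal overlap >= %g):\n", x$min_fraction))
  cat(sprintf("  set A: %d enhancers, %d shared, %d unique\n",
              x$n_a, x$n_shared_a, x$n_unique_a))
  cat(sprintf("  set B: %d enhancers, %d shared, %d unique\n",
              x$n_b, x$n_shared_b, x$n_unique_b))
  cat(sprintf("  fraction of union shared: %.3f; Venn components: %d shared / %d A-only / %d B-only\n",
              x$fraction_shared_union, x$venn_shared, x$venn_unique_a,
              x$venn_unique_b))
  invisible(x)
}

#' Summarise an enhancer set
#'
#' Counts, stretch fraction, and a length histogram.
#'
#' @param set an `enhancer_set` from [call_enhancers()].
#' @param hist_bin_bp histogram bin width in bp.
#' @return List with `n_enhancers`, `n_stretch`, `stretch_fraction`
#'   (`NaN` with a warning for an empty set), and `length_histogram`
#'   (`data.frame` of bin starts and counts).
#' @export
stretch_summary <- function(set, hist_bin_bp = 500L) {
  n <- nrow(set)
  if (n == 0L) {
    warning("empty enhancer set: stretch fraction undefined")
    return(list(n_enhancers = 0L, n_stretch = 0L, stretch_fraction = NaN,
                length_histogram = data.frame(bin_start = integer(0),
                                              count = integer(0))))
  }
  len <- set$end - set$start
  bins <- floor(len / hist_bin_bp) * hist_bin_bp
  tab <- table(bins)
  list(n_enhancers = n, n_stretch = sum(set$is_stretch),
       stretch_fraction = sum(set$is_stretch) / n,
       length_histogram = data.frame(bin_start = as.integer(names(tab)),
                                     count = as.integer(tab)))
}
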