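#' Classify peak sharing between two conditions
#'
#' A peak in one set is "shared" when it overlaps any peak of the other set
#' by at least `min_overlap_bp` bases (default 1 bp, the weakest defensible
#' convention). Also reports overlap components: maximal groups of mutually
#' linked peaks across the union of both sets.
#'
#' @param peaks_a,peaks_b [peak_set()]s (plain interval data.frames accepted).
#' @param min_overlap_bp minimum overlap in bp (>= 1).
#' @return List of class `"peak_sharing"`: `shared_a`, `shared_b` (logical
#'   per peak), counts `n_a`, `n_b`, `n_shared_a`, `n_shared_b`,
#'   `n_a_only`, `n_b_only`, and `n_shared_components` (components containing
#'   peaks from both sets).
#' @export
classify_peak_sharing <- function(peaks_a, peaks_b, min_overlap_bp = 1L) {
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  pr <- overlap_pairs(peaks_a, peaks_b, min_overlap = min_overlap_bp)
  shared_a <- seq_len(nrow(peaks_a)) %in% pr$i
  shared_b <- seq_len(nrow(peaks_b)) %in% pr$j
  n_ab <- nrow(peaks_a) + nrow(peaks_b)
  parent <- seq_len(n_ab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pr))) {
    ra <- find(pr$i[k]); rb <- find(nrow(peaks_a) + pr$j[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n_ab), find, 1L)
  is_a <- seq_len(n_ab) <= nrow(peaks_a)
  both <- tapply(is_a, roots, any) & tapply(!is_a, roots, any)
  structure(list(
    shared_a = shared_a, shared_b = shared_b,
    n_a = nrow(peaks_a), n_b = nrow(peaks_b),
    n_shared_a = sum(shared_a), n_shared_b = sum(shared_b),
    n_a_only = sum(!shared_a), n_b_only = sum(!shared_b),
    n_shared_components = sum(both),
    min_overlap_bp = min_overlap_bp), class = "peak_sharing")
}

#' @export
print.peak_sharing <- function(x, ...) {
  cat(sprintf("Peak sharing (>= %d bp overlap): A %d (%d shared), B %d (%d shared), %d shared components\n",
              x$min_overlap_bp, x$n_a, x$n_shared_a, x$n_b, x$n_shared_b,
              x$n_shared_components))
  invisible(x)
}

#' TSS-proximal peaks
#'
#' A peak is TSS-proximal when the nearest transcription start site is within
#' `max_dist` bp of the peak ([min_distance()] convention: 0 inside the
#' peak, else distance to the nearest covered base). Default 1 kb.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_table()]; must be non-empty.
#' @param max_dist inclusive distance threshold in bp.
#' @return List with `proximal` (logical per peak), `subset` (the proximal
#'   peaks), and `fraction`.
#' @export
tss_proximal_fraction <- function(peaks, genes, max_dist = 1000L) {
  if (max_dist < 0) stop("max_dist must be >= 0")
  if (nrow(genes) == 0L) stop("gene list is empty")
  d <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == ch)
    tss <- sort(genes$tss[genes$chrom == ch])
    if (length(tss) == 0L) next
    s <- peaks$start[sel]; e <- peaks$end[sel]
    k <- findInterval(e - 1L, tss)           # rightmost TSS <= end - 1
    lo <- ifelse(k >= 1L, tss[pmax(k, 1L)], NA_integer_)
    hi <- ifelse(k < length(tss), tss[pmin(k + 1L, length(tss))], NA_integer_)
    dd <- pmin(
      ifelse(is.na(lo), Inf, ifelse(lo >= s, 0, s - lo)),
      ifelse(is.na(hi), Inf, hi - (e - 1L)))
    d[sel] <- dd
  }
  proximal <- d <= max_dist
  list(proximal = proximal,
       subset = peaks[proximal, , drop = FALSE],
       fraction = mean(proximal))
}

#' Chromatin state at peak midpoints
#'
#' Returns the state of the segment covering each peak's midpoint base
#' `floor((start + end) / 2)`, or `NA` ("unmarked") when no segment covers
#' it.
#'
#' @param peaks a [peak_set()] (or interval data.frame).
#' @param seg a [segmentation()].
#' @return Integer vector of states with `NA` for unmarked midpoints.
#' @export
site_state <- function(peaks, seg) {
  mids <- interval_midpoint(peaks$start, peaks$end)
  out <- rep(NA_integer_, nrow(peaks))
  s <- seg$segments
  for (ch in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == ch)
    sc <- s[s$chrom == ch, , drop = FALSE]
    if (nrow(sc) == 0L) next
    idx <- findInterval(mids[sel], sc$start)
    hit <- idx >= 1L
    hit[hit] <- mids[sel][hit] < sc$end[idx[hit]]
    out[sel][hit] <- sc$state[idx[hit]]
  }
  out
}

#' Chromatin-state transition class of binding sites
#'
#' Classifies each site from its sharing label between conditions A
#' (progenitor) and B (differentiated) and its chromatin state in each:
#' * `repressed_to_active`: B-only, not active in A, active in B;
#' * `active_to_active`: shared, active in both;
#' * `active_to_repressed`: A-only, active in A, not active in B;
#' * `other`: everything else.
#' "Unmarked" (`NA` state) counts as not active.
#'
#' @param sharing character vector in `c("shared", "a_only", "b_only")`.
#' @param state_a,state_b integer states (`NA` = unmarked).
#' @param active_states integer set of active states; default `1:6`.
#' @return Factor with levels `repressed_to_active`, `active_to_active`,
#'   `active_to_repressed`, `other`.
#' @export
transition_class <- function(sharing, state_a, state_b, active_states = 1:6) {
  stopifnot(all(sharing %in% c("shared", "a_only", "b_only")))
  act_a <- !is.na(state_a) & state_a %in% active_states
  act_b <- !is.na(state_b) & state_b %in% active_states
  cls <- rep("other", length(sharing))
  cls[sharing == "b_only" & !act_a & act_b] <- "repressed_to_active"
  cls[sharing == "shared" & act_a & act_b] <- "active_to_active"
  cls[sharing == "a_only" & act_a & !act_b] <- "active_to_repressed"
  factor(cls, levels = c("repressed_to_active", "active_to_active",
                         "active_to_repressed", "other"))
}

#' Aggregate signal profile around peak midpoints
#'
#' Averages a step-function signal track in fixed-width bins of offsets
#' relative to each anchor midpoint, then averages over anchors. Windows
#' running past chromosome bounds are clipped with per-bin denominators
#' adjusted.
#'
#' @param anchors a [peak_set()] (non-empty).
#' @param track a [signal_track()].
#' @param half_window half-width of the profile window in bp (default 1000).
#' @param bin_width bin width in bp (must divide `half_window`).
#' @param chrom_lengths optional named vector of chromosome lengths used for
#'   right-edge clipping (left edge is always clipped at 0).
#' @return List of class `"profile_matrix"`: `offset` (bin left edges
#'   relative to the midpoint), `value` (mean signal per bin), `n_anchors`,
#'   `half_window`, `bin_width`.
#' @export
aggregate_profile <- function(anchors, track, half_window = 1000L,
                              bin_width = 10L, chrom_lengths = NULL) {
  if (nrow(anchors) == 0L) stop("empty anchor set")
  if (half_window %% bin_width != 0L)
    stop("half_window must be a multiple of bin_width")
  n_bins <- 2L * half_window / bin_width
  offsets <- seq(-half_window, half_window - bin_width, by = bin_width)
  sums <- numeric(n_bins)
  denom <- numeric(n_bins)
  mids <- interval_midpoint(anchors$start, anchors$end)
  rel <- seq(-half_window, half_window - 1L)
  bin_of <- rep(seq_len(n_bins), each = bin_width)
  for (i in seq_len(nrow(anchors))) {
    pos <- mids[i] + rel
    keep <- pos >= 0L
    if (!is.null(chrom_lengths) && anchors$chrom[i] %in% names(chrom_lengths))
      keep <- keep & pos < chrom_lengths[[anchors$chrom[i]]]
    v <- track_values_at(track, rep(anchors$chrom[i], sum(keep)), pos[keep])
    b <- bin_of[keep]
    sums <- sums + vapply(split(v, factor(b, levels = seq_len(n_bins))), sum, 0)
    denom <- denom + tabulate(b, nbins = n_bins)
  }
  value <- unname(sums / ifelse(denom > 0, denom, NA_real_))
  structure(list(offset = offsets, value = value,
                 n_anchors = nrow(anchors), half_window = half_window,
                 bin_width = bin_width), class = "profile_matrix")
}

#' Fraction of reads in peaks (FRiP)
#'
#' The ENCODE-style signal-to-noise metric: the fraction of read intervals
#' overlapping any peak by at least 1 bp.
#'
#' @param reads interval `data.frame` of read spans (>= 1 read).
#' @param peaks a [peak_set()].
#' @return A single number in `[0, 1]`.
#' @export
frip <- function(reads, peaks) {
  if (nrow(reads) == 0L) stop("no reads supplied")
  if (nrow(peaks) == 0L) return(0)
  merged <- merge_intervals(peaks[, c("chrom", "start", "end")], max_gap = 0L)
  hit <- logical(nrow(reads))
  for (ch in unique(reads$chrom)) {
    sel <- which(reads$chrom == ch)
    m <- merged[merged$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0L) next
    # a read [s, e) overlaps some merged peak iff the first peak with
    # end > s exists and has start < e
    j <- findInterval(reads$start[sel], m$end) + 1L
    ok <- j <= nrow(m)
    ok[ok] <- m$start[j[ok]] < reads$end[sel][ok]
    hit[sel] <- ok
  }
  mean(hit)
}
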