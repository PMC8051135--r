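#' Motif-density profile around classified binding sites
#'
#' For each site class, extracts `half_window` bp either side of every site
#' midpoint, scans the window with the PWM at a relative-score threshold, and
#' bins the hit-center offsets. The reported density is hits per bp per site,
#' so summing `density * bin_width` over the window gives the mean number of
#' hits per site. Overlapping hits are all counted. Windows truncated by
#' chromosome ends are clipped, with per-bin denominators adjusted.
#'
#' @param sites a [peak_set()]-like `data.frame`; when `classes` is `NULL`
#'   a `class` column of `sites` is used (all sites as one class `"all"` if
#'   absent).
#' @param genome named character vector of chromosome sequences (see
#'   [read_fasta()]).
#' @param p a [pwm()].
#' @param classes optional vector assigning a class label to each site.
#' @param half_window half window in bp (default 500).
#' @param bin_width bin width in bp (default 10).
#' @param rel_threshold relative-score threshold (default 0.8).
#' @param both_strands scan both strands (default `TRUE`).
#' @return Named list (one element per class) of `"profile_matrix"` lists:
#'   `offset` (bin left edges), `value` (hits/bp/site), `n_anchors`,
#'   `half_window`, `bin_width`, `motif_id`.
#' @export
motif_density_profile <- function(sites, genome, p, classes = NULL,
                                  half_window = 500L, bin_width = 10L,
                                  rel_threshold = 0.8, both_strands = TRUE) {
  if (half_window %% bin_width != 0L)
    stop("half_window must be a multiple of bin_width")
  if (is.null(classes))
    classes <- if (!is.null(sites$class)) sites$class else rep("all", nrow(sites))
  stopifnot(length(classes) == nrow(sites))
  if (!all(sites$chrom %in% names(genome)))
    stop("sites reference chromosomes absent from the genome")
  n_bins <- 2L * half_window / bin_width
  offsets <- seq(-half_window, half_window - bin_width, by = bin_width)
  mids <- interval_midpoint(sites$start, sites$end)
  out <- list()
  for (cl in unique(as.character(classes))) {
    idx <- which(as.character(classes) == cl)
    counts <- numeric(n_bins)
    denom <- numeric(n_bins)
    for (i in idx) {
      clen <- nchar(genome[[sites$chrom[i]]])
      lo <- max(0L, mids[i] - half_window)
      hi <- min(clen, mids[i] + half_window)
      if (hi <= lo) next
      win <- substr(genome[[sites$chrom[i]]], lo + 1L, hi)
      hits <- scan_sequence(win, p, rel_threshold = rel_threshold,
                            both_strands = both_strands,
                            chrom = sites$chrom[i], offset = lo)
      if (nrow(hits)) {
        centers <- interval_midpoint(hits$start, hits$end) - mids[i]
        b <- floor((centers + half_window) / bin_width) + 1L
        b <- b[b >= 1L & b <= n_bins]
        counts <- counts + tabulate(b, nbins = n_bins)
      }
      # bases of each bin actually scannable for hit centers in this window
      cov_lo <- lo - mids[i]; cov_hi <- hi - mids[i]
      bin_lo <- pmax(offsets, cov_lo); bin_hi <- pmin(offsets + bin_width, cov_hi)
      denom <- denom + pmax(bin_hi - bin_lo, 0)
    }
    out[[cl]] <- structure(
      list(offset = offsets,
           value = counts / ifelse(denom > 0, denom, NA_real_),
           n_anchors = length(idx), half_window = half_window,
           bin_width = bin_width, motif_id = p$motif_id),
      class = "profile_matrix")
  }
  out
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("Profile over %d anchors: %d bins of %d bp (+/- %d bp)%s\n",
              x$n_anchors, length(x$offset), x$bin_width, x$half_window,
              if (!is.null(x$motif_id)) paste0(", motif ", x$motif_id) else ""))
  invisible(x)
}

#' Export motif hits as BED6
#'
#' Score column is `round(1000 * rel_score)`.
#'
#' @param hits a [scan_sequence()] result with resolved `chrom`.
#' @param path output path.
#' @export
write_motif_hits_bed <- function(hits, path) {
  write_bed(data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
                       name = hits$motif_id,
                       score = round(1000 * hits$rel_score),
                       strand = hits$strand, stringsAsFactors = FALSE),
            path)
}
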