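#' Chromatin-state segmentation
#'
#' An ordered, per-chromosome non-overlapping set of labeled state segments,
#' the in-memory surrogate for a ChromHMM `*_segments.bed` file. Gaps between
#' segments are allowed and treated as "unmarked" chromatin.
#'
#' @param segments `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `state` (integer in `1..state_count`).
#' @param state_count number of states in the model (11 for the study design
#'   this package targets).
#' @param resolution informational bin size in bp.
#' @return An object of class `"segmentation"`.
#' @export
segmentation <- function(segments, state_count = 11L, resolution = 200L) {
  validate_intervals(segments, "segment")
  stopifnot(is.numeric(segments$state))
  if (any(segments$state < 1 | segments$state > state_count))
    stop(sprintf("state labels must be in 1..%d", state_count))
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  ov <- with(segments, chrom[-1L] == chrom[-length(chrom)] &
               start[-1L] < end[-length(end)])
  if (length(ov) && any(ov))
    stop(sprintf("overlapping segments at row(s) %s",
                 paste(utils::head(which(ov) + 1L, 5L), collapse = ", ")))
  structure(list(segments = segments,
                 state_count = as.integer(state_count),
                 resolution = as.integer(resolution)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Chromatin-state segmentation: %d segments, %d states, %d chromosome(s)\n",
              nrow(x$segments), x$state_count, length(unique(x$segments$chrom))))
  invisible(x)
}

#' Peak set
#'
#' A labelled collection of genomic intervals (TF binding sites, ATAC peaks).
#' Peaks within a set may overlap each other.
#'
#' @param peaks interval `data.frame`; optional columns `name`, `score`.
#' @param label condition or assay label.
#' @return A `data.frame` of class `"peak_set"`, sorted by `(chrom, start)`,
#'   with attribute `label`.
#' @export
peak_set <- function(peaks, label = "peaks") {
  validate_intervals(peaks, "peak")
  if (!is.null(peaks$score) && any(!is.finite(peaks$score) & !is.na(peaks$score)))
    stop("peak scores must be finite")
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, label = label, class = c("peak_set", "data.frame"))
}

#' Expression matrix
#'
#' Gene-level FPKM values per condition, with the naive pseudocount
#' log2 fold-change used throughout the package:
#' `log2fc = log2((FPKM_b + 1) / (FPKM_a + 1))`.
#'
#' @param x `data.frame` with a `gene_id` column and one numeric FPKM column
#'   per condition.
#' @param conditions character vector naming the condition columns; defaults
#'   to all non-`gene_id` columns. Order matters: the last condition is taken
#'   as the differentiated state by downstream defaults.
#' @return A `data.frame` of class `"expression_matrix"`.
#' @export
expression_matrix <- function(x, conditions = setdiff(names(x), "gene_id")) {
  stopifnot("gene_id" %in% names(x), length(conditions) >= 1)
  if (anyDuplicated(x$gene_id)) stop("gene_id must be unique")
  for (cc in conditions) {
    if (any(x[[cc]] < 0)) stop(sprintf("negative FPKM in condition '%s'", cc))
  }
  structure(as.data.frame(x), conditions = conditions,
            class = c("expression_matrix", "data.frame"))
}

#' Log2 fold-change between two conditions
#'
#' @param expr an [expression_matrix()].
#' @param cond_a,cond_b condition column names (defaults: first and last).
#' @return Named numeric vector, `log2((FPKM_b + 1)/(FPKM_a + 1))` per gene.
#' @export
expression_log2fc <- function(expr,
                              cond_a = attr(expr, "conditions")[1L],
                              cond_b = rev(attr(expr, "conditions"))[1L]) {
  stats::setNames(log2((expr[[cond_b]] + 1) / (expr[[cond_a]] + 1)),
                  expr$gene_id)
}

#' Gene annotation table
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `tss` (0-based bp).
#' @return Validated `data.frame` of class `"gene_table"`.
#' @export
gene_table <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id must be unique")
  if (any(genes$tss < 0)) stop("tss must be >= 0")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  structure(as.data.frame(genes), class = c("gene_table", "data.frame"))
}

#' Step-function signal track (bedGraph semantics)
#'
#' @param steps `data.frame` with columns `chrom`, `start`, `end`, `value`;
#'   steps must not overlap within a chromosome. Uncovered bases have value 0.
#' @return A `data.frame` of class `"signal_track"`.
#' @export
signal_track <- function(steps) {
  validate_intervals(steps, "step")
  stopifnot(is.numeric(steps$value))
  steps <- steps[order(steps$chrom, steps$start), , drop = FALSE]
  rownames(steps) <- NULL
  ov <- with(steps, chrom[-1L] == chrom[-length(chrom)] &
               start[-1L] < end[-length(end)])
  if (length(ov) && any(ov)) stop("signal track steps overlap")
  structure(steps, class = c("signal_track", "data.frame"))
}

# step-function lookup: value of the track at each (chrom, pos); 0 off-track
track_values_at <- function(track, chrom, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    st <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(st) == 0L) next
    idx <- findInterval(pos[sel], st$start)
    v <- numeric(sum(sel))
    hit <- idx >= 1L
    hit[hit] <- pos[sel][hit] < st$end[idx[hit]]
    v[hit] <- st$value[idx[hit]]
    out[sel] <- v
  }
  out
}
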