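#' Position weight matrix
#'
#' A probability PWM over \{A, C, G, T\} with a background distribution.
#' Scores are log2 odds `log2(p[base, j] / background[base])` summed over
#' positions; the relative score of a window is min-max normalised,
#' `(score - min_score) / (max_score - min_score)`, so the JASPAR-style
#' "80% threshold" is `rel_score >= 0.8`.
#'
#' @param matrix 4 x L numeric matrix of probabilities, rows `A, C, G, T`,
#'   each column summing to 1 (tolerance 1e-6).
#' @param motif_id motif identifier.
#' @param background length-4 background probabilities (default uniform).
#' @return An object of class `"pwm"`.
#' @export
pwm <- function(matrix, motif_id = "motif", background = rep(0.25, 4)) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4L, ncol(matrix) >= 1L)
  rownames(matrix) <- c("A", "C", "G", "T")
  if (any(abs(colSums(matrix) - 1) > 1e-6))
    stop("each PWM column must sum to 1")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background must sum to 1")
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, consensus %s\n", x$motif_id,
              ncol(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Convert a JASPAR count matrix to a probability PWM
#'
#' Adds a pseudocount to every cell before normalising each column, so all
#' probabilities are strictly positive and log odds are finite.
#'
#' @param counts 4 x L count matrix (rows A, C, G, T), e.g. one element of
#'   [read_jaspar_pfm()].
#' @param motif_id motif identifier (defaults to the matrix `"name"`
#'   attribute, if any).
#' @param pseudocount added to every cell; default 0.25.
#' @param background background probabilities.
#' @return A [pwm()].
#' @export
as_pwm <- function(counts, motif_id = NULL, pseudocount = 0.25,
                   background = rep(0.25, 4)) {
  if (is.null(motif_id))
    motif_id <- attr(counts, "name") %||% "motif"
  m <- counts + pseudocount
  m <- sweep(m, 2L, colSums(m), "/")
  pwm(m, motif_id = motif_id, background = background)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pwm_consensus <- function(p) {
  paste(c("A", "C", "G", "T")[apply(p$matrix, 2L, which.max)], collapse = "")
}

pwm_logodds <- function(p) {
  if (any(p$matrix <= 0))
    stop("PWM has zero-probability cells; apply a pseudocount first")
  log2(p$matrix / p$background)
}

#' Attainable score bounds of a PWM
#'
#' Minimum and maximum log2-odds score over all possible sequences of the
#' motif's length; per position these are the column minima/maxima, so the
#' bounds are their sums. Used to normalise scores to `[0, 1]`.
#'
#' @param p a [pwm()].
#' @return Named numeric vector `c(min_score, max_score)` in bits.
#' @export
pwm_score_bounds <- function(p) {
  w <- pwm_logodds(p)
  c(min_score = sum(apply(w, 2L, min)), max_score = sum(apply(w, 2L, max)))
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

seq_codes <- function(seq) {
  unname(DNA_CODE[strsplit(toupper(seq), "", fixed = TRUE)[[1]]])
}

revcomp_pwm <- function(p) {
  m <- p$matrix[4:1, ncol(p$matrix):1, drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm(m, motif_id = p$motif_id, background = p$background[4:1])
}

# log-odds score of every window start (NA where the window contains N)
window_scores <- function(codes, w) {
  L <- ncol(w)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) sc <- sc + w[, j][codes[seq_len(n) + j - 1L]]
  sc
}

#' Scan a sequence with a PWM
#'
#' Reports every window whose relative score reaches `rel_threshold`, on both
#' strands if requested. Minus-strand windows are scored with the
#' reverse-complemented PWM and reported in forward-strand coordinates.
#' Windows containing `N` are skipped.
#'
#' @param seq DNA string over `A, C, G, T, N`.
#' @param p a [pwm()].
#' @param rel_threshold relative-score threshold in (0, 1]; default 0.8, the
#'   JASPAR-style 80% confidence level.
#' @param both_strands scan the reverse strand too (default `TRUE`).
#' @param chrom optional chromosome name recorded in the hits.
#' @param offset added to hit coordinates (for scanning an excised window of
#'   a larger sequence).
#' @return `data.frame` with columns `motif_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `score` (bits), `rel_score`.
#' @export
scan_sequence <- function(seq, p, rel_threshold = 0.8, both_strands = TRUE,
                          chrom = NA_character_, offset = 0L) {
  if (rel_threshold <= 0 || rel_threshold > 1)
    stop("rel_threshold must be in (0, 1]")
  codes <- seq_codes(seq)
  b <- pwm_score_bounds(p)
  span <- b[["max_score"]] - b[["min_score"]]
  hits <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    w <- pwm_logodds(if (strand == "+") p else revcomp_pwm(p))
    sc <- window_scores(codes, w)
    rel <- if (span > 0) (sc - b[["min_score"]]) / span else as.numeric(sc >= sc)
    keep <- which(!is.na(rel) & rel >= rel_threshold)
    if (length(keep))
      hits[[strand]] <- data.frame(
        motif_id = p$motif_id, chrom = chrom,
        start = keep - 1L + as.integer(offset),
        end = keep - 1L + ncol(p$matrix) + as.integer(offset),
        strand = strand, score = sc[keep], rel_score = rel[keep],
        stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(motif_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      rel_score = numeric(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
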