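#' Count distinct stretch enhancers near a gene set
#'
#' Number of distinct stretch enhancers having at least one gene-set TSS
#' within `half_window` bp ([min_distance()] convention, inclusive). An
#' enhancer near several genes counts once. The default window is 50 kb each
#' side of the TSS (a 100-kb span).
#'
#' @param genes a [gene_table()] restricted to the gene set.
#' @param stretch `data.frame` of stretch enhancers (rows with
#'   `is_stretch = TRUE` of an `enhancer_set`; validated).
#' @param half_window inclusive distance threshold in bp.
#' @return Integer count.
#' @export
count_proximal_stretch_enhancers <- function(genes, stretch,
                                             half_window = 50000L) {
  if (!is.null(stretch$is_stretch) && !all(stretch$is_stretch))
    stop("'stretch' must contain only stretch enhancers")
  if (nrow(genes) == 0L) {
    warning("empty gene set")
    return(0L)
  }
  adj <- proximal_enhancer_index(genes, stretch, half_window)
  length(unique(unlist(adj, use.names = FALSE)))
}

# per-gene list of global row indices of (disjoint, sorted) enhancers whose
# distance to the gene's TSS is <= half_window
proximal_enhancer_index <- function(genes, enh, half_window) {
  o <- order(enh$chrom, enh$start)
  out <- rep(list(integer(0)), nrow(genes))
  for (ch in unique(genes$chrom)) {
    gsel <- which(genes$chrom == ch)
    esel <- o[enh$chrom[o] == ch]
    if (length(esel) == 0L) next
    starts <- enh$start[esel]; ends1 <- enh$end[esel] - 1L
    cm <- cummax(ends1)                      # handles overlapping inputs
    tss <- genes$tss[gsel]
    lo <- findInterval(tss - half_window - 1L, cm) + 1L
    hi <- findInterval(tss + half_window, starts)
    for (k in seq_along(gsel)) {
      if (hi[k] < lo[k]) next
      cand <- lo[k]:hi[k]
      out[[gsel[k]]] <- esel[cand[ends1[cand] >= tss[k] - half_window]]
    }
  }
  out
}

#' Empirical p-value of a permutation null
#'
#' The paper-facing convention `p = #\{null >= observed\} / N` (so 2 of
#' 10,000 gives 0.0002), plus the add-one estimate
#' `(k + 1) / (N + 1)` as the statistically safer value.
#'
#' @param observed observed statistic.
#' @param null_counts vector of null statistics.
#' @return List with `empirical_p` and `empirical_p_add_one`.
#' @export
empirical_pvalue <- function(observed, null_counts) {
  k <- sum(null_counts >= observed)
  n <- length(null_counts)
  list(empirical_p = k / n, empirical_p_add_one = (k + 1) / (n + 1))
}

#' Expression-matched random gene sets
#'
#' Bins every universe gene into `n_bins` quantile bins of
#' `log10(FPKM + 1)` in the chosen condition, then draws, for each target
#' gene, one non-target gene uniformly without replacement from the same
#' bin. The sampled set therefore reproduces the target's bin occupancy
#' exactly.
#'
#' @param expr an [expression_matrix()] over the gene universe.
#' @param target_ids gene ids of the target set (all present in `expr`).
#' @param n_bins number of quantile bins (default 10).
#' @param condition condition used for matching; default the last
#'   (differentiated) condition.
#' @return Character vector of sampled gene ids, same length as
#'   `target_ids`. Uses the current RNG stream.
#' @export
expression_matched_sample <- function(expr, target_ids, n_bins = 10L,
                                      condition = rev(attr(expr, "conditions"))[1L]) {
  prep <- matched_sampler_prep(expr, target_ids, n_bins, condition)
  draw_matched(prep)
}

matched_sampler_prep <- function(expr, target_ids, n_bins, condition) {
  if (!all(target_ids %in% expr$gene_id))
    stop("target genes missing from the expression universe")
  if (nrow(expr) < 2L * length(target_ids))
    stop("universe must be at least twice the target-set size")
  x <- log10(expr[[condition]] + 1)
  breaks <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                            type = 7, names = FALSE)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  is_target <- expr$gene_id %in% target_ids
  need <- tabulate(bin[is_target], nbins = n_bins)
  pools <- lapply(seq_len(n_bins), function(b)
    expr$gene_id[bin == b & !is_target])
  short <- which(need > lengths(pools))
  if (length(short))
    stop(sprintf("bin %s has fewer available non-target genes than needed",
                 paste(short, collapse = ", ")))
  list(pools = pools, need = need, bin_width = diff(breaks), x = x,
       gene_id = expr$gene_id)
}

draw_matched <- function(prep) {
  picks <- character(0)
  for (b in which(prep$need > 0L)) {
    pool <- prep$pools[[b]]
    k <- prep$need[b]
    picks <- c(picks, pool[sample.int(length(pool), k)])
  }
  picks
}

#' Expression-matched permutation test for stretch-enhancer enrichment
#'
#' Tests whether a signature gene set has more distinct stretch enhancers
#' within `half_window` of its TSSs than expression-matched random gene sets
#' of the same size. The observed statistic is
#' [count_proximal_stretch_enhancers()]; the null is built from
#' `n_perm` expression-matched resamples ([expression_matched_sample()]);
#' the empirical p-value is `#\{null >= observed\} / n_perm` with the
#' add-one estimate reported alongside.
#'
#' @param target_ids signature gene ids.
#' @param genes [gene_table()] for the whole universe.
#' @param expr [expression_matrix()] for the whole universe.
#' @param stretch stretch enhancers (see
#'   [count_proximal_stretch_enhancers()]).
#' @param n_perm number of permutations (default 10000).
#' @param half_window proximity window in bp each side of the TSS
#'   (default 50000).
#' @param n_bins expression-matching quantile bins (default 10).
#' @param seed integer seed making the test fully reproducible; `NULL` uses
#'   the current RNG state.
#' @param condition matching condition; default the last one.
#' @return Object of class `"permutation_result"`: `observed`,
#'   `null_counts`, `n_permutations`, `empirical_p`, `empirical_p_add_one`,
#'   `seed`, `parameters`.
#' @export
permutation_enrichment_test <- function(target_ids, genes, expr, stretch,
                                        n_perm = 10000L, half_window = 50000L,
                                        n_bins = 10L, seed = NULL,
                                        condition = rev(attr(expr, "conditions"))[1L]) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  genes <- genes[match(expr$gene_id, genes$gene_id), , drop = FALSE]
  if (any(is.na(genes$gene_id)))
    stop("expression universe contains genes absent from the annotation")
  adj <- proximal_enhancer_index(genes, stretch, half_window)
  names(adj) <- genes$gene_id
  observed <- length(unique(unlist(adj[target_ids], use.names = FALSE)))
  prep <- matched_sampler_prep(expr, target_ids, n_bins, condition)
  null_counts <- integer(n_perm)
  for (r in seq_len(n_perm)) {
    ids <- draw_matched(prep)
    null_counts[r] <- length(unique(unlist(adj[ids], use.names = FALSE)))
  }
  pv <- empirical_pvalue(observed, null_counts)
  if (pv$empirical_p == 0)
    warning(sprintf("no null count reached the observed value; add-one estimate 1/%d",
                    n_perm + 1L))
  structure(list(observed = observed, null_counts = null_counts,
                 n_permutations = n_perm,
                 empirical_p = pv$empirical_p,
                 empirical_p_add_one = pv$empirical_p_add_one,
                 seed = seed,
                 parameters = list(half_window = half_window, n_bins = n_bins,
                                   set_size = length(target_ids),
                                   condition = condition)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Expression-matched permutation test (%d genes, +/- %d bp, %d permutations)\n",
              x$parameters$set_size, x$parameters$half_window, x$n_permutations))
  cat(sprintf("  observed proximal stretch enhancers: %d\n", x$observed))
  cat(sprintf("  null mean %.2f (range %d-%d)\n", mean(x$null_counts),
              min(x$null_counts), max(x$null_counts)))
  cat(sprintf("  empirical p = %.4g (add-one estimate %.4g)\n",
              x$empirical_p, x$empirical_p_add_one))
  invisible(x)
}

#' Bound versus unbound promoter expression test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing FPKM of genes
#' whose promoters are bound against all other genes. Uses the exact
#' distribution when both groups have at most 20 observations and no ties,
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param expr an [expression_matrix()].
#' @param bound_ids gene ids of the bound group (non-empty; the unbound
#'   group is its non-empty complement).
#' @param condition condition column to compare.
#' @return List with `U` (number of (bound, unbound) pairs won by bound,
#'   ties counting half), `p_value`, `exact`, group sizes.
#' @export
bound_vs_unbound_expression_test <- function(expr, bound_ids,
                                             condition = rev(attr(expr, "conditions"))[1L]) {
  is_bound <- expr$gene_id %in% bound_ids
  x <- expr[[condition]][is_bound]
  y <- expr[[condition]][!is_bound]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  exact <- length(x) <= 20L && length(y) <= 20L &&
    !any(duplicated(c(x, y)))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact,
       n_bound = length(x), n_unbound = length(y))
}

#' Log2 fold-change of the nearest gene to each enhancer
#'
#' For each enhancer, finds the gene with the smallest
#' [min_distance()] between its TSS and the enhancer (ties broken by the
#' lexicographically smaller `gene_id`) and returns its pseudocount log2
#' fold-change, grouped by enhancer label.
#'
#' @param enhancers interval `data.frame` of enhancers.
#' @param labels grouping label per enhancer (e.g. `"a_specific"`,
#'   `"b_specific"`, `"shared"`).
#' @param genes a [gene_table()] (non-empty).
#' @param expr an [expression_matrix()].
#' @param cond_a,cond_b conditions for the fold-change (defaults: first and
#'   last).
#' @return Named list (one numeric vector of log2 fold-changes per label);
#'   enhancers on chromosomes with no annotated gene are dropped with a
#'   warning.
#' @export
nearest_gene_log2fc <- function(enhancers, labels, genes, expr,
                                cond_a = attr(expr, "conditions")[1L],
                                cond_b = rev(attr(expr, "conditions"))[1L]) {
  if (nrow(genes) == 0L) stop("gene list is empty")
  stopifnot(length(labels) == nrow(enhancers))
  lfc <- expression_log2fc(expr, cond_a, cond_b)
  nearest <- character(nrow(enhancers))
  for (i in seq_len(nrow(enhancers))) {
    g <- genes[genes$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) { nearest[i] <- NA_character_; next }
    d <- min_distance(enhancers$chrom[i], enhancers$start[i], enhancers$end[i],
                      g$tss, g$chrom)
    cand <- g$gene_id[d == min(d)]
    nearest[i] <- sort(cand)[1L]
  }
  if (anyNA(nearest)) {
    warning("dropping enhancer(s) on chromosomes with no annotated gene")
    keep <- !is.na(nearest)
    nearest <- nearest[keep]; labels <- labels[keep]
  }
  split(unname(lfc[nearest]), labels)
}

#' One-way fixed-effects ANOVA
#'
#' Classical F statistic `MS_between / MS_within` with a p-value from the
#' `F(k - 1, n - k)` distribution.
#'
#' @param groups list of `k >= 2` numeric vectors, each of length >= 2.
#' @return List with `F`, `p_value`, `df` (length-2 vector).
#' @export
group_expression_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least two values")
  n <- sum(lengths(groups))
  k <- length(groups)
  grand <- mean(unlist(groups))
  ss_between <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1L; df2 <- n - k
  if (ss_within == 0 && ss_between == 0) {
    warning("all groups constant with equal means; p = 1 by convention")
    return(list(F = NaN, p_value = 1, df = c(df1, df2)))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

#' Select the top percent of differentially expressed genes
#'
#' Ranks expressed genes (FPKM > 0 in either condition) by pseudocount log2
#' fold-change and returns the most extreme `ceil(percent% * n_expressed)`
#' in the requested direction.
#'
#' @param expr an [expression_matrix()].
#' @param percent percentage in (0, 100); default 5.
#' @param direction `"up"` (highest log2 fold-change, condition B enriched)
#'   or `"down"`.
#' @param cond_a,cond_b conditions (defaults: first and last).
#' @return Character vector of gene ids.
#' @export
select_top_percent_de <- function(expr, percent = 5,
                                  direction = c("up", "down"),
                                  cond_a = attr(expr, "conditions")[1L],
                                  cond_b = rev(attr(expr, "conditions"))[1L]) {
  direction <- match.arg(direction)
  if (percent <= 0 || percent >= 100) stop("percent must be in (0, 100)")
  expressed <- expr[[cond_a]] > 0 | expr[[cond_b]] > 0
  lfc <- expression_log2fc(expr, cond_a, cond_b)[expressed]
  n <- ceiling(percent / 100 * sum(expressed))
  o <- order(lfc, decreasing = (direction == "up"))
  names(lfc)[o[seq_len(n)]]
}

#' Co-staining proportion
#'
#' Integer percentage of double-positive cells among marker-positive cells,
#' rounded half up (so 8/26 is 31% and 8/270 is 3%).
#'
#' @param n_double double-positive count.
#' @param n_marker marker-positive count (>= 1).
#' @return List of class `"proportion_report"`: `numerator`, `denominator`,
#'   `percent`.
#' @export
costain_proportions <- function(n_double, n_marker) {
  if (n_marker < 1L) stop("n_marker must be >= 1")
  if (n_double < 0L || n_double > n_marker)
    stop("need 0 <= n_double <= n_marker")
  structure(list(numerator = as.integer(n_double),
                 denominator = as.integer(n_marker),
                 percent = as.integer(floor(100 * n_double / n_marker + 0.5))),
            class = "proportion_report")
}

#' @export
print.proportion_report <- function(x, ...) {
  cat(sprintf("%d%% (%d/%d)\n", x$percent, x$numerator, x$denominator))
  invisible(x)
}
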