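test_that("proximal stretch-enhancer counts deduplicate and respect the window", {
  enh <- data.frame(chrom = "c1", start = 0L, end = 1000L, is_stretch = TRUE)
  g <- function(tss) gene_table(data.frame(gene_id = sprintf("g%d", seq_along(tss)),
                                           chrom = "c1", strand = "+", tss = tss))
  # distance from TSS 51000 to last covered base 999 is 50001: outside
  expect_equal(count_proximal_stretch_enhancers(g(51000L), enh), 0L)
  expect_equal(count_proximal_stretch_enhancers(g(50999L), enh), 1L)
  # an enhancer near two set genes counts once
  expect_equal(count_proximal_stretch_enhancers(g(c(100L, 2000L)), enh), 1L)
  expect_warning(n0 <- count_proximal_stretch_enhancers(g(1L)[0, ], enh), "empty")
  expect_equal(n0, 0L)
  expect_error(count_proximal_stretch_enhancers(
    g(1L), data.frame(chrom = "c1", start = 0L, end = 10L, is_stretch = FALSE)),
    "stretch")

  set.seed(51)
  for (rep in 1:10) {
    enh <- random_intervals(60, max_pos = 100000, max_len = 5000)
    gn <- gene_table(data.frame(gene_id = sprintf("g%d", 1:40),
                                chrom = sample(c("chr1", "chr2", "chr3"), 40, TRUE),
                                strand = "+", tss = sample.int(105000, 40)))
    w <- sample(c(1000L, 10000L, 30000L), 1)
    expect_equal(count_proximal_stretch_enhancers(gn, enh, w),
                 oracle_count_proximal(gn, enh, w))
  }
})

test_that("empirical p follows the k/N convention with add-one alongside", {
  null <- c(rep(0L, 9998L), 30L, 31L)
  pv <- empirical_pvalue(28L, null)
  expect_equal(pv$empirical_p, 0.0002)
  expect_equal(pv$empirical_p_add_one, 3 / 10001)
  expect_equal(empirical_pvalue(0L, c(0L, 1L, 2L))$empirical_p, 1)
  # monotone in the observed value for a fixed null vector
  ps <- vapply(0:32, function(o) empirical_pvalue(o, null)$empirical_p, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("expression-matched samples reproduce the target bin occupancy", {
  set.seed(52)
  expr <- expression_matrix(data.frame(
    gene_id = sprintf("g%03d", 1:300),
    progenitor = round(rlnorm(300, 2, 1.2), 4),
    differentiated = round(rlnorm(300, 2, 1.2), 4)))
  target <- sample(expr$gene_id, 20)
  x <- log10(expr$differentiated + 1)
  br <- quantile(x, seq(0, 1, 0.1), type = 7, names = FALSE)
  bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  names(bin) <- expr$gene_id
  for (rep in 1:20) {
    s <- expression_matched_sample(expr, target)
    expect_equal(tabulate(bin[s], 10L), tabulate(bin[target], 10L))
    expect_length(intersect(s, target), 0)
    expect_false(anyDuplicated(s) > 0)
  }
  # uniformity within a single bin: 1 target, pool of 9
  small <- expression_matrix(data.frame(gene_id = sprintf("u%d", 1:10),
                                        progenitor = 1,
                                        differentiated = rep(5, 10)))
  draws <- replicate(9000, expression_matched_sample(small, "u1", n_bins = 1L))
  freq <- table(draws) / 9000
  expect_length(freq, 9)
  se <- sqrt((1 / 9) * (8 / 9) / 9000)
  expect_true(all(abs(freq - 1 / 9) < 3 * se + 1e-9))
})

test_that("matched sampling errors when a bin runs out of partners", {
  expr <- expression_matrix(data.frame(gene_id = sprintf("v%d", 1:8),
                                       progenitor = 1,
                                       differentiated = c(1, 1, 1, 1, 9, 9, 9, 9)))
  expect_error(expression_matched_sample(expr, c("v5", "v6", "v7"), n_bins = 2L),
               "bin")
})

test_that("rank-sum test: worked example, tied identity, enumeration oracle", {
  expr3 <- expression_matrix(data.frame(gene_id = sprintf("g%d", 1:6),
                                        a = 1, b = c(1, 2, 3, 4, 5, 6)))
  r <- bound_vs_unbound_expression_test(expr3, c("g1", "g2", "g3"), "b")
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)

  same <- expression_matrix(data.frame(gene_id = sprintf("g%d", 1:6),
                                       a = 1, b = rep(c(1, 2, 3), 2)))
  expect_equal(bound_vs_unbound_expression_test(same, c("g1", "g2", "g3"),
                                                "b")$p_value, 1)

  set.seed(53)
  for (rep in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    vals <- round(sample(seq(0.5, 60, 0.5), n1 + n2), 4)  # tie-free
    expr <- expression_matrix(data.frame(
      gene_id = sprintf("g%d", seq_len(n1 + n2)), a = 1, b = vals))
    r <- bound_vs_unbound_expression_test(expr, sprintf("g%d", 1:n1), "b")
    expect_true(r$exact)
    expect_equal(r$p_value, oracle_mw_exact(vals[1:n1], vals[-(1:n1)]),
                 tolerance = 1e-9)
  }
})

test_that("nearest-gene fold-changes pick the closest TSS with lexicographic ties", {
  genes <- gene_table(data.frame(gene_id = c("gB", "gA", "gC"),
                                 chrom = "c1", strand = "+",
                                 tss = c(500L, 10000L, 150L)))
  expr <- expression_matrix(data.frame(gene_id = c("gB", "gA", "gC"),
                                       a = c(1, 1, 1), b = c(3, 7, 15)))
  enh <- data.frame(chrom = "c1", start = 0L, end = 100L)
  # gC at distance 51 beats gB at 401
  out <- nearest_gene_log2fc(enh, "x", genes, expr)
  expect_equal(out$x, log2(16 / 2))
  # equidistant: TSS 200 and 398 around last covered base 99/start 0
  genes2 <- gene_table(data.frame(gene_id = c("gB", "gA"), chrom = "c1",
                                  strand = "+", tss = c(250L, 450L)))
  enh2 <- data.frame(chrom = "c1", start = 300L, end = 400L)
  # distances: gB 50, gA 51 -> gB; make them equal:
  genes3 <- gene_table(data.frame(gene_id = c("gB", "gA"), chrom = "c1",
                                  strand = "+", tss = c(250L, 449L)))
  expr2 <- expression_matrix(data.frame(gene_id = c("gB", "gA"),
                                        a = c(1, 1), b = c(3, 7)))
  expect_equal(nearest_gene_log2fc(enh2, "x", genes3, expr2)$x, log2(7 + 1) - 1)
})

test_that("one-way ANOVA matches hand calculation and oneway.test", {
  same <- group_expression_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)

  r <- group_expression_anova(list(c(1, 2), c(5, 6)))
  expect_equal(r$F, 32)
  expect_equal(r$p_value, pf(32, 1, 2, lower.tail = FALSE))
  expect_equal(round(r$p_value, 4), 0.0299)

  expect_warning(z <- group_expression_anova(list(c(2, 2), c(2, 2))), "convention")
  expect_equal(z$p_value, 1)

  set.seed(54)
  for (rep in 1:20) {
    g <- lapply(1:sample(2:5, 1), function(i) rnorm(sample(3:10, 1), mean = i / 2))
    r <- group_expression_anova(g)
    ot <- oneway.test(v ~ grp, data.frame(
      v = unlist(g), grp = rep(seq_along(g), lengths(g))), var.equal = TRUE)
    expect_equal(r$F, unname(ot$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, ot$p.value, tolerance = 1e-12)
  }
})

test_that("top-percent DE selection ranks expressed genes by log2 fold-change", {
  set.seed(55)
  n <- 200
  expr <- expression_matrix(data.frame(
    gene_id = sprintf("g%03d", 1:n),
    a = c(round(rlnorm(n - 50, 1, 1), 4), rep(0, 50)),
    b = c(round(rlnorm(n - 50, 1, 1), 4), rep(0, 50))))
  up <- select_top_percent_de(expr, 5, "up")
  lfc <- expression_log2fc(expr)
  expressed <- expr$a > 0 | expr$b > 0
  expect_length(up, ceiling(0.05 * sum(expressed)))
  expect_equal(sort(up),
               sort(names(sort(lfc[expressed], decreasing = TRUE))[seq_along(up)]))
  dn <- select_top_percent_de(expr, 5, "down")
  expect_equal(sort(dn),
               sort(names(sort(lfc[expressed]))[seq_along(dn)]))
})
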