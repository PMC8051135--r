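test_that("peak sharing uses >= 1 bp half-open overlap and is role-symmetric", {
  a <- peak_set(data.frame(chrom = "c1", start = 0L, end = 100L))
  b1 <- peak_set(data.frame(chrom = "c1", start = 99L, end = 150L))
  b2 <- peak_set(data.frame(chrom = "c1", start = 100L, end = 150L))
  expect_true(classify_peak_sharing(a, b1)$shared_a)
  expect_false(classify_peak_sharing(a, b2)$shared_a)

  set.seed(31)
  for (rep in 1:10) {
    pa <- peak_set(random_intervals(50))
    pb <- peak_set(random_intervals(50))
    fwd <- classify_peak_sharing(pa, pb)
    rev_ <- classify_peak_sharing(pb, pa)
    expect_equal(fwd$n_a_only, rev_$n_b_only)
    expect_equal(fwd$n_b_only, rev_$n_a_only)
    expect_equal(fwd$n_shared_components, rev_$n_shared_components)
  }
})

test_that("TSS proximity is inclusive at the threshold and matches the oracle", {
  genes <- function(tss) gene_table(data.frame(gene_id = "g1", chrom = "c1",
                                               strand = "+", tss = tss))
  pk <- peak_set(data.frame(chrom = "c1", start = 100L, end = 200L))
  expect_true(tss_proximal_fraction(pk, genes(1199L))$proximal)
  expect_false(tss_proximal_fraction(pk, genes(1200L))$proximal)
  expect_error(tss_proximal_fraction(pk, genes(1L)[0, ]), "empty")

  set.seed(32)
  for (rep in 1:10) {
    pk <- peak_set(random_intervals(100))
    gn <- gene_table(data.frame(gene_id = sprintf("g%d", 1:60),
                                chrom = sample(c("chr1", "chr2", "chr3"), 60,
                                               replace = TRUE),
                                strand = "+",
                                tss = sample.int(5200, 60)))
    d <- sample(c(0L, 50L, 500L), 1)
    expect_equal(tss_proximal_fraction(pk, gn, d)$proximal,
                 oracle_tss_proximal(pk, gn, d))
  }
})

test_that("the midpoint base decides the site state; gaps are unmarked", {
  seg <- segmentation(data.frame(chrom = "c1", start = c(0L, 200L, 600L),
                                 end = c(200L, 400L, 800L),
                                 state = c(3L, 8L, 1L)))
  pk <- data.frame(chrom = "c1",
                   start = c(0L, 450L, 100L),
                   end = c(180L, 550L, 320L))
  # midpoints 90 (E3), 500 (gap), 210 (straddles 3|8 -> state at 210 = 8)
  expect_equal(site_state(pk, seg), c(3L, NA, 8L))
})

test_that("transition classes follow the definitions and partition all sites", {
  expect_equal(as.character(transition_class("b_only", 8L, 2L)),
               "repressed_to_active")
  expect_equal(as.character(transition_class("shared", 1L, 6L)),
               "active_to_active")
  expect_equal(as.character(transition_class("a_only", 4L, NA)),
               "active_to_repressed")
  expect_equal(as.character(transition_class("shared", 7L, 2L)), "other")

  set.seed(33)
  sharing <- sample(c("shared", "a_only", "b_only"), 500, replace = TRUE)
  sa <- sample(c(1:11, NA), 500, replace = TRUE)
  sb <- sample(c(1:11, NA), 500, replace = TRUE)
  cls <- transition_class(sharing, sa, sb)
  expect_equal(sum(table(cls)), 500L)
  expect_false(anyNA(cls))
})

test_that("aggregate profiles average the track per offset bin", {
  anchors <- peak_set(data.frame(chrom = "c1", start = 4000L, end = 4400L))
  flat <- signal_track(data.frame(chrom = "c1", start = 0L, end = 10000L,
                                  value = 2.5))
  pr <- aggregate_profile(anchors, flat, half_window = 500L, bin_width = 10L)
  expect_equal(length(pr$value), 100L)
  expect_true(all(abs(pr$value - 2.5) < 1e-12))

  # random step track vs direct per-bp averaging
  set.seed(34)
  steps <- data.frame(chrom = "c1",
                      start = seq(0L, 9900L, by = 100L),
                      end = seq(100L, 10000L, by = 100L),
                      value = round(runif(100), 3))
  tr <- signal_track(steps)
  anch <- peak_set(data.frame(chrom = "c1",
                              start = c(2000L, 5150L, 7777L),
                              end = c(2400L, 5350L, 8111L)))
  pr <- aggregate_profile(anch, tr, half_window = 200L, bin_width = 20L)
  mids <- floor((anch$start + anch$end) / 2)
  want <- sapply(seq_along(pr$offset), function(k) {
    mean(sapply(mids, function(m) {
      pos <- m + pr$offset[k] + 0:19
      mean(track_values_at(tr, rep("c1", 20), pos))
    }))
  })
  expect_equal(pr$value, want, tolerance = 1e-12)

  # the aggregate equals the unweighted mean of single-anchor profiles
  singles <- sapply(seq_len(nrow(anch)), function(i)
    aggregate_profile(anch[i, ], tr, half_window = 200L, bin_width = 20L)$value)
  expect_equal(pr$value, rowMeans(singles), tolerance = 1e-12)

  expect_error(aggregate_profile(anch[0, ], tr), "empty")
})

test_that("FRiP counts reads overlapping any peak", {
  reads <- data.frame(chrom = "c1", start = seq(0L, 900L, 100L),
                      end = seq(50L, 950L, 100L))
  peaks <- peak_set(data.frame(chrom = "c1", start = c(0L, 120L, 820L),
                               end = c(40L, 140L, 830L)))
  expect_equal(frip(reads, peaks), 0.3)
  expect_equal(frip(reads, peaks[0, ]), 0)
  expect_error(frip(reads[0, ], peaks), "reads")

  set.seed(35)
  for (rep in 1:10) {
    rd <- random_intervals(300, max_len = 80)
    pk <- peak_set(random_intervals(40, max_len = 300))
    want <- mean(vapply(seq_len(nrow(rd)), function(i) {
      any(pk$chrom == rd$chrom[i] & pk$start < rd$end[i] & pk$end > rd$start[i])
    }, TRUE))
    expect_equal(frip(rd, pk), want)
  }
})
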