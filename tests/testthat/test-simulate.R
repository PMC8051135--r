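small_config <- function(...) {
  args <- utils::modifyList(
    list(chrom_lengths = c(chr1 = 400000L, chr2 = 400000L),
         n_genes = 300L, n_bound_genes = 30L,
         signature_set_size = 0L, n_sites = 300L),
    list(...))
  do.call(simulation_config, args)
}

test_that("the state chain is deterministic under a seed and absorbs under identity", {
  cfg <- small_config(seed = 7L)
  expect_equal(simulate_segmentation(cfg, "progenitor"),
               simulate_segmentation(cfg, "progenitor"))
  expect_false(identical(simulate_segmentation(cfg, "progenitor"),
                         simulate_segmentation(cfg, "differentiated")))

  ident <- simulation_config(chrom_lengths = c(chr1 = 100000L, chr2 = 60000L),
                             transition_matrix = diag(11), initial_state = 5L)
  seg <- simulate_segmentation(ident)
  expect_equal(nrow(seg$segments), 2L)
  expect_true(all(seg$segments$state == 5L))
  expect_equal(seg$segments$end - seg$segments$start, c(100000L, 60000L))
})

test_that("a uniform transition matrix gives uniform state occupancy", {
  n_bins <- 50000L
  cfg <- simulation_config(seed = 5L,
                           chrom_lengths = c(chr1 = n_bins * 200L),
                           transition_matrix = matrix(1 / 11, 11, 11))
  seg <- simulate_segmentation(cfg)
  occ <- tapply(seg$segments$end - seg$segments$start, seg$segments$state, sum)
  freq <- occ / sum(occ)
  se <- sqrt((1 / 11) * (10 / 11) / n_bins)
  expect_true(all(abs(freq - 1 / 11) < 3.5 * se))
})

test_that("non-stochastic transition matrices are rejected", {
  bad <- matrix(1 / 11, 11, 11); bad[1, 1] <- 0.5
  expect_error(simulation_config(transition_matrix = bad), "stochastic")
})

test_that("promoter-bound expression boosts are planted at the stated size", {
  ratios <- vapply(1:10, function(s) {
    cfg <- small_config(seed = s, n_genes = 2000L, n_bound_genes = 200L,
                        promoter_bound_boost = 4)
    ge <- simulate_genes_expression(cfg)
    bound <- ge$expr$gene_id %in% ge$truth$bound_genes
    median(ge$expr$differentiated[bound]) /
      median(ge$expr$differentiated[!bound])
  }, 0)
  expect_true(abs(mean(ratios) - 4) / 4 < 0.25)

  # null case: no boost, similar medians
  cfg0 <- small_config(seed = 3L, promoter_bound_boost = 1)
  ge0 <- simulate_genes_expression(cfg0)
  bound <- ge0$expr$gene_id %in% ge0$truth$bound_genes
  p <- wilcox.test(ge0$expr$differentiated[bound],
                   ge0$expr$differentiated[!bound])$p.value
  expect_gt(p, 1e-4)
})

test_that("every planted signature TSS lies within the window of its enhancer", {
  cfg <- simulation_config(seed = 9L, signature_window = 1000L)
  ds <- simulate_dataset(cfg, what = "genes")
  sig <- ds$truth$signature
  expect_equal(nrow(sig), 25L)
  expect_false(anyDuplicated(paste(sig$enh_chrom, sig$enh_start)) > 0)
  tss <- ds$genes$tss[match(sig$gene_id, ds$genes$gene_id)]
  d <- min_distance(sig$enh_chrom, sig$enh_start, sig$enh_end, tss,
                    ds$genes$chrom[match(sig$gene_id, ds$genes$gene_id)])
  expect_true(all(d <= 1000))
})

test_that("too few stretch enhancers for the signature set is an error", {
  cfg <- small_config()
  expect_error(
    simulate_genes_expression(
      simulation_config(signature_set_size = 25L),
      stretch_b = data.frame(chrom = "chr1", start = 0L, end = 4000L)[0, ]),
    "fewer stretch enhancers")
})

test_that("site class mixes are honoured, including the degenerate ones", {
  seg <- lapply(c("progenitor", "differentiated"), function(cc)
    simulate_segmentation(small_config(seed = 2L), cc))
  cfg_all_shared <- small_config(seed = 2L,
                                 site_class_probs = c(shared = 1, a_only = 0,
                                                      b_only = 0))
  pk <- simulate_peaks(cfg_all_shared, seg[[1]], seg[[2]])
  expect_equal(as.data.frame(pk$peaks_a), as.data.frame(pk$peaks_b),
               ignore_attr = TRUE)

  cfg_a_only <- small_config(seed = 2L, n_sites = 100L,
                             site_class_probs = c(shared = 0, a_only = 1,
                                                  b_only = 0))
  pk <- simulate_peaks(cfg_a_only, seg[[1]], seg[[2]])
  expect_equal(nrow(pk$peaks_b), 0L)
  expect_gt(nrow(pk$peaks_a), 0L)
})

test_that("downstream sharing classification recovers the planted site classes", {
  cfg <- small_config(seed = 4L)
  seg_a <- simulate_segmentation(cfg, "progenitor")
  seg_b <- simulate_segmentation(cfg, "differentiated")
  pk <- simulate_peaks(cfg, seg_a, seg_b)
  sh <- classify_peak_sharing(pk$peaks_a, pk$peaks_b)
  got_a <- ifelse(sh$shared_a, "shared", "a_only")
  truth_a <- pk$sites$class[match(pk$peaks_a$name, pk$sites$site_id)]
  expect_gte(mean(got_a == truth_a), 0.99)
  got_b <- ifelse(sh$shared_b, "shared", "b_only")
  truth_b <- pk$sites$class[match(pk$peaks_b$name, pk$sites$site_id)]
  expect_gte(mean(got_b == truth_b), 0.99)
})

test_that("planted motifs sit at their recorded offsets and scan at rel 1", {
  cfg <- small_config(seed = 6L, motif_plant_prob = 1)
  ds <- simulate_dataset(cfg, what = c("peaks", "sequences"))
  tr <- ds$truth$motifs
  expect_gt(nrow(tr), 0)
  cons <- vapply(cfg$motif_families, pwm_consensus, "")
  for (k in sample.int(nrow(tr), 50)) {
    s <- substr(ds$genome[[tr$chrom[k]]], tr$start[k] + 1L, tr$start[k] + 8L)
    expect_identical(s, cons[[tr$motif_id[k]]])
  }
  # every site has some plant at offset 0
  planted_sites <- unique(tr$site_id[tr$offset == 0])
  expect_setequal(planted_sites, ds$sites$site_id)
})

test_that("dataset generation is a pure function of the config", {
  cfg <- small_config(seed = 8L, n_sites = 100L, n_genes = 120L,
                      n_bound_genes = 12L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("truth tables stay within chromosome bounds", {
  cfg <- small_config(seed = 10L)
  ds <- simulate_dataset(cfg)
  lens <- cfg$chrom_lengths
  expect_true(all(ds$sites$end <= lens[ds$sites$chrom]))
  expect_true(all(ds$sites$start >= 0))
  expect_true(all(ds$genes$tss < lens[ds$genes$chrom]))
  m <- ds$truth$motifs
  expect_true(all(m$start >= 0 & m$start + 8 <= lens[m$chrom]))
  expect_true(all(m$site_id %in% ds$sites$site_id))
})
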