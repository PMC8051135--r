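## Synthetic paired-condition dataset generator. Everything downstream of a
## real experiment (segmentations, peaks, expression, genome sequence,
## signal tracks) is generated with planted, ground-truth-known structure so
## each pipeline stage can be tested against the truth tables.

#' Default chromatin-state transition matrix
#'
#' First-order Markov transition matrix over the 11 chromatin states used by
#' the simulator. Enhancer states form a sticky block (stay probability
#' 0.84 within the block, so enhancer runs are geometric with about 7% of
#' them exceeding 15 bins = 3 kb) and carry a stationary mass of about 0.15,
#' giving roughly 720 enhancers and 50 stretch enhancers per condition on the
#' default 6-Mb genome.
#'
#' @param state_count number of states.
#' @param enhancer_states the sticky enhancer block (default `c(2, 3)`).
#' @param enhancer_stay probability of keeping the exact enhancer state.
#' @param enhancer_cross probability of switching to the other enhancer
#'   state.
#' @param other_stay self-transition probability of non-enhancer states.
#' @param to_enhancer probability of a non-enhancer state moving to each
#'   enhancer state.
#' @return `state_count` x `state_count` row-stochastic matrix.
#' @export
default_transition_matrix <- function(state_count = 11L,
                                      enhancer_states = c(2L, 3L),
                                      enhancer_stay = 0.76,
                                      enhancer_cross = 0.08,
                                      other_stay = 0.70,
                                      to_enhancer = 0.0141) {
  S <- state_count
  other <- setdiff(seq_len(S), enhancer_states)
  m <- matrix(0, S, S)
  leak <- (1 - enhancer_stay - enhancer_cross) / length(other)
  for (i in enhancer_states) {
    m[i, i] <- enhancer_stay
    m[i, setdiff(enhancer_states, i)] <- enhancer_cross / max(1L, length(enhancer_states) - 1L)
    m[i, other] <- leak
  }
  spread <- (1 - other_stay - to_enhancer * length(enhancer_states)) /
    (length(other) - 1L)
  for (i in other) {
    m[i, i] <- other_stay
    m[i, enhancer_states] <- to_enhancer
    m[i, setdiff(other, i)] <- spread
  }
  m
}

#' Default planted motif families
#'
#' Four synthetic 8-bp motif families standing in for the factor classes
#' profiled around binding sites: a POU-like octamer, a bZIP-like TRE, an
#' HTH-like and a bHLH-like E-box motif. Each PWM puts probability
#' `sharpness` on the consensus base and the rest uniformly on the others.
#'
#' @param sharpness consensus-base probability (default 0.85).
#' @return Named list of [pwm()]s
#'   (`pou_like`, `bzip_like`, `hth_like`, `bhlh_like`).
#' @export
default_motif_families <- function(sharpness = 0.85) {
  cons <- c(pou_like = "ATGCAAAT", bzip_like = "TGACTCAG",
            hth_like = "GTTGCCAT", bhlh_like = "ACAGCTGT")
  lapply(stats::setNames(names(cons), names(cons)), function(nm) {
    bases <- strsplit(cons[[nm]], "")[[1]]
    m <- matrix((1 - sharpness) / 3, 4L, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(bases)) m[bases[j], j] <- sharpness
    pwm(m, motif_id = nm)
  })
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic dataset. Defaults describe the
#' desk-scale study design: a 3 x 2 Mb genome segmented at 200-bp
#' resolution into 11 chromatin states, ~1500 genes with log-normal FPKM, a
#' 4-fold expression boost for promoter-bound genes, a 25-gene signature set
#' relocated next to differentiated-condition stretch enhancers, and 4000
#' binding sites (3000 peaks per condition) in shared/unique classes with
#' class-specific planted motifs.
#'
#' @param seed master seed; each component (segmentation, genes, peaks,
#'   sequence, signal) derives its own sub-stream from it.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param bin_size segmentation resolution (bp).
#' @param state_count number of chromatin states.
#' @param enhancer_states,active_states state sets used throughout.
#' @param transition_matrix a row-stochastic matrix, or a list of two (one
#'   per condition); default [default_transition_matrix()].
#' @param initial_state fixed initial chain state, or `NULL` for uniform.
#' @param conditions the two condition names (progenitor, differentiated).
#' @param n_genes number of genes.
#' @param fpkm_meanlog,fpkm_sdlog log-normal FPKM parameters.
#' @param promoter_bound_boost multiplicative FPKM boost, in the
#'   differentiated condition, of bound genes.
#' @param n_bound_genes number of bound genes.
#' @param signature_set_size signature genes relocated near distinct
#'   differentiated-condition stretch enhancers (0 disables planting).
#' @param signature_window maximum distance (bp) between a planted signature
#'   TSS and its stretch enhancer.
#' @param n_sites total binding sites across classes.
#' @param site_class_probs probabilities of classes
#'   `(shared, a_only, b_only)`.
#' @param site_slot site spacing grid (bp); one site at most per slot keeps
#'   sites from overlapping.
#' @param peak_width_range min/max peak width (bp).
#' @param state_purity fraction of condition-unique sites constrained to
#'   bins active in their own condition and inactive in the other.
#' @param motif_plant_prob per-site, per-family planting probability.
#' @param motif_families named list of [pwm()]s
#'   (see [default_motif_families()]).
#' @param stretch_min_bp,max_gap enhancer-calling parameters carried in the
#'   config.
#' @param signal_height,signal_baseline,signal_step triangular-bump signal
#'   track parameters.
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 2000000L,
                                                chr2 = 2000000L,
                                                chr3 = 2000000L),
                              bin_size = 200L,
                              state_count = 11L,
                              enhancer_states = c(2L, 3L),
                              active_states = 1:6,
                              transition_matrix = NULL,
                              initial_state = NULL,
                              conditions = c("progenitor", "differentiated"),
                              n_genes = 1500L,
                              fpkm_meanlog = 2,
                              fpkm_sdlog = 1.2,
                              promoter_bound_boost = 4,
                              n_bound_genes = 150L,
                              signature_set_size = 25L,
                              signature_window = 10000L,
                              n_sites = 4000L,
                              site_class_probs = c(shared = 0.5,
                                                   a_only = 0.25,
                                                   b_only = 0.25),
                              site_slot = 1200L,
                              peak_width_range = c(200L, 600L),
                              state_purity = 0.9,
                              motif_plant_prob = 0.5,
                              motif_families = default_motif_families(),
                              stretch_min_bp = 3000L,
                              max_gap = 1L,
                              signal_height = 10,
                              signal_baseline = 0.5,
                              signal_step = 20L) {
  if (is.null(transition_matrix))
    transition_matrix <- default_transition_matrix(state_count, enhancer_states)
  tms <- if (is.list(transition_matrix)) transition_matrix else
    list(transition_matrix, transition_matrix)
  for (tm in tms) {
    if (!is.matrix(tm) || any(dim(tm) != state_count) ||
        any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0))
      stop("transition matrix must be row-stochastic over the state set")
  }
  stopifnot(bin_size >= 1L, n_genes > 0L, n_sites >= 0L,
            length(conditions) == 2L,
            abs(sum(site_class_probs) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 bin_size = as.integer(bin_size),
                 state_count = as.integer(state_count),
                 enhancer_states = enhancer_states,
                 active_states = active_states,
                 transition_matrix = tms, initial_state = initial_state,
                 conditions = conditions, n_genes = as.integer(n_genes),
                 fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
                 promoter_bound_boost = promoter_bound_boost,
                 n_bound_genes = as.integer(n_bound_genes),
                 signature_set_size = as.integer(signature_set_size),
                 signature_window = as.integer(signature_window),
                 n_sites = as.integer(n_sites),
                 site_class_probs = site_class_probs,
                 site_slot = as.integer(site_slot),
                 peak_width_range = as.integer(peak_width_range),
                 state_purity = state_purity,
                 motif_plant_prob = motif_plant_prob,
                 motif_families = motif_families,
                 stretch_min_bp = as.integer(stretch_min_bp),
                 max_gap = as.integer(max_gap),
                 signal_height = signal_height,
                 signal_baseline = signal_baseline,
                 signal_step = as.integer(signal_step)),
            class = "simulation_config")
}

# independent sub-stream seeds so changing one component's parameters does
# not perturb the others
component_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

#' Simulate a chromatin-state segmentation
#'
#' Runs a first-order Markov chain over the states at bin resolution on each
#' chromosome, then collapses runs of equal state into segments. A trailing
#' partial bin (chromosome length not a multiple of `bin_size`) is dropped.
#'
#' @param config a [simulation_config()].
#' @param condition one of `config$conditions`.
#' @return A [segmentation()].
#' @export
simulate_segmentation <- function(config, condition = config$conditions[1L]) {
  ci <- match(condition, config$conditions)
  if (is.na(ci)) stop("unknown condition")
  set.seed(component_seed(config$seed, 10L + ci))
  tm <- config$transition_matrix[[ci]]
  cum <- t(apply(tm, 1L, cumsum))
  S <- config$state_count
  segs <- list()
  for (ch in names(config$chrom_lengths)) {
    n_bins <- config$chrom_lengths[[ch]] %/% config$bin_size
    if (n_bins == 0L) next
    s <- integer(n_bins)
    s[1L] <- if (is.null(config$initial_state))
      sample.int(S, 1L) else as.integer(config$initial_state)
    if (n_bins > 1L) {
      u <- stats::runif(n_bins - 1L)
      for (i in 2:n_bins) {
        s[i] <- findInterval(u[i - 1L], cum[s[i - 1L], ]) + 1L
      }
    }
    run_end <- c(which(s[-1L] != s[-n_bins]), n_bins)
    run_start <- c(1L, utils::head(run_end, -1L) + 1L)
    segs[[ch]] <- data.frame(
      chrom = ch,
      start = (run_start - 1L) * config$bin_size,
      end = run_end * config$bin_size,
      state = s[run_start], stringsAsFactors = FALSE)
  }
  segmentation(do.call(rbind, c(segs, list(make.row.names = FALSE))),
               state_count = S, resolution = config$bin_size)
}

#' Simulate genes and expression with planted structure
#'
#' TSSs are uniform over the genome and FPKM is log-normal per condition
#' (rounded to 4 decimals so files round-trip exactly). Two structures are
#' planted: a random "bound" gene subset whose differentiated-condition FPKM
#' is multiplied by `promoter_bound_boost`, and a signature set of
#' `signature_set_size` genes relocated so each TSS lies within
#' `signature_window` bp of a distinct differentiated-condition stretch
#' enhancer.
#'
#' @param config a [simulation_config()].
#' @param stretch_b stretch enhancers of the differentiated condition
#'   (rows of an `enhancer_set` with `is_stretch = TRUE`); only needed when
#'   `signature_set_size > 0`.
#' @return List with `genes` ([gene_table()]), `expr`
#'   ([expression_matrix()]), and `truth` (`bound_genes`,
#'   `signature` table of gene ids and their planted enhancers).
#' @export
simulate_genes_expression <- function(config, stretch_b = NULL) {
  set.seed(component_seed(config$seed, 20L))
  n <- config$n_genes
  lens <- config$chrom_lengths
  chrom <- sample(names(lens), n, replace = TRUE,
                  prob = lens / sum(lens))
  tss <- vapply(chrom, function(ch) sample.int(lens[[ch]], 1L) - 1L, 1L)
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
                      chrom = chrom,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      tss = as.integer(tss), stringsAsFactors = FALSE)
  fpkm <- vapply(config$conditions, function(cc)
    round(stats::rlnorm(n, config$fpkm_meanlog, config$fpkm_sdlog), 4L),
    numeric(n))
  bound <- sort(sample.int(n, config$n_bound_genes))
  fpkm[bound, 2L] <- round(fpkm[bound, 2L] * config$promoter_bound_boost, 4L)
  sig <- data.frame(gene_id = character(0), enh_chrom = character(0),
                    enh_start = integer(0), enh_end = integer(0))
  if (config$signature_set_size > 0L) {
    if (is.null(stretch_b) || nrow(stretch_b) < config$signature_set_size)
      stop("fewer stretch enhancers than signature_set_size")
    pick_enh <- sample.int(nrow(stretch_b), config$signature_set_size)
    pick_gene <- sample(setdiff(seq_len(n), bound), config$signature_set_size)
    for (k in seq_len(config$signature_set_size)) {
      e <- stretch_b[pick_enh[k], ]
      lo <- max(0L, e$start - config$signature_window)
      hi <- min(lens[[e$chrom]] - 1L, e$end - 1L + config$signature_window)
      genes$chrom[pick_gene[k]] <- e$chrom
      genes$tss[pick_gene[k]] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    }
    sig <- data.frame(gene_id = genes$gene_id[pick_gene],
                      enh_chrom = stretch_b$chrom[pick_enh],
                      enh_start = stretch_b$start[pick_enh],
                      enh_end = stretch_b$end[pick_enh],
                      stringsAsFactors = FALSE)
  }
  expr <- data.frame(gene_id = genes$gene_id, fpkm,
                     stringsAsFactors = FALSE)
  names(expr) <- c("gene_id", config$conditions)
  list(genes = gene_table(genes),
       expr = expression_matrix(expr, config$conditions),
       truth = list(bound_genes = genes$gene_id[bound], signature = sig))
}

# per-bin state vectors for one chromosome of a segmentation
bin_states <- function(seg, ch, n_bins, bin_size) {
  s <- seg$segments[seg$segments$chrom == ch, , drop = FALSE]
  out <- rep(NA_integer_, n_bins)
  if (nrow(s)) {
    from <- s$start %/% bin_size + 1L
    to <- pmin((s$end - 1L) %/% bin_size + 1L, n_bins)
    for (i in seq_len(nrow(s))) out[from[i]:to[i]] <- s$state[i]
  }
  out
}

#' Simulate binding sites in shared/unique classes
#'
#' Sites are drawn in three ground-truth classes: `shared` (identical
#' interval in both conditions), `a_only` and `b_only` (placed, with
#' probability `state_purity`, in bins active in their own condition and
#' inactive in the other). At most one site per `site_slot` bp grid slot, so
#' sites never overlap and the sharing truth is exact.
#'
#' @param config a [simulation_config()].
#' @param seg_a,seg_b segmentations of the two conditions.
#' @return List with `sites` (truth table: `site_id`, `chrom`, `start`,
#'   `end`, `class`) and [peak_set()]s `peaks_a`, `peaks_b`.
#' @export
simulate_peaks <- function(config, seg_a, seg_b) {
  set.seed(component_seed(config$seed, 30L))
  bs <- config$bin_size
  bins <- list()
  for (ch in names(config$chrom_lengths)) {
    n_bins <- config$chrom_lengths[[ch]] %/% bs
    bstart <- (seq_len(n_bins) - 1L) * bs
    slot <- bstart %/% config$site_slot
    # drop first and last slot per chromosome so peaks never cross an edge,
    # and keep only the interior bins of each slot so sites in adjacent
    # slots stay far enough apart never to overlap
    margin <- bstart %% config$site_slot
    keep <- slot > 0L & slot < max(slot) &
      margin >= bs & margin < config$site_slot - 2L * bs
    bins[[ch]] <- data.frame(
      chrom = ch, bin_start = bstart,
      state_a = bin_states(seg_a, ch, n_bins, bs),
      state_b = bin_states(seg_b, ch, n_bins, bs),
      slot = paste0(ch, ":", slot),
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  bins <- do.call(rbind, c(bins, list(make.row.names = FALSE)))
  act <- function(s) !is.na(s) & s %in% config$active_states
  elig_a <- act(bins$state_a) & !act(bins$state_b)
  elig_b <- act(bins$state_b) & !act(bins$state_a)
  p <- config$site_class_probs
  n_shared <- round(p[["shared"]] * config$n_sites)
  n_aonly <- round(p[["a_only"]] * config$n_sites)
  n_bonly <- config$n_sites - n_shared - n_aonly
  used_slots <- character(0)
  pick_bins <- function(n_constrained, n_free, elig) {
    picked <- integer(0)
    if (n_constrained > 0L) {
      avail <- which(elig & !(bins$slot %in% used_slots))
      avail_slots <- unique(bins$slot[avail])
      if (length(avail_slots) < n_constrained)
        stop("requested peak count exceeds available eligible bins")
      slots <- sample(avail_slots, n_constrained)
      picked <- vapply(slots, function(sl) {
        cand <- avail[bins$slot[avail] == sl]
        cand[sample.int(length(cand), 1L)]
      }, 1L)
      used_slots <<- c(used_slots, slots)
    }
    if (n_free > 0L) {
      avail <- which(!(bins$slot %in% used_slots))
      avail_slots <- unique(bins$slot[avail])
      if (length(avail_slots) < n_free)
        stop("requested peak count exceeds available eligible bins")
      slots <- sample(avail_slots, n_free)
      free_pick <- vapply(slots, function(sl) {
        cand <- avail[bins$slot[avail] == sl]
        cand[sample.int(length(cand), 1L)]
      }, 1L)
      used_slots <<- c(used_slots, slots)
      picked <- c(picked, free_pick)
    }
    picked
  }
  n_ac <- round(config$state_purity * n_aonly)
  n_bc <- round(config$state_purity * n_bonly)
  idx_a <- pick_bins(n_ac, n_aonly - n_ac, elig_a)
  idx_b <- pick_bins(n_bc, n_bonly - n_bc, elig_b)
  idx_s <- pick_bins(0L, n_shared, NULL)
  idx <- c(idx_a, idx_b, idx_s)
  classes <- rep(c("a_only", "b_only", "shared"),
                 c(length(idx_a), length(idx_b), length(idx_s)))
  mid <- bins$bin_start[idx] + bs %/% 2L +
    sample.int(161L, length(idx), replace = TRUE) - 81L   # jitter +/- 80
  width <- 2L * sample(seq(config$peak_width_range[1L] %/% 2L,
                           config$peak_width_range[2L] %/% 2L),
                       length(idx), replace = TRUE)
  sites <- data.frame(site_id = sprintf("site%05d", seq_along(idx)),
                      chrom = bins$chrom[idx],
                      start = as.integer(mid - width %/% 2L),
                      end = as.integer(mid + width %/% 2L),
                      class = classes, stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  mk <- function(cls, label) {
    sel <- sites$class %in% cls
    peak_set(data.frame(chrom = sites$chrom[sel], start = sites$start[sel],
                        end = sites$end[sel], name = sites$site_id[sel],
                        stringsAsFactors = FALSE), label = label)
  }
  list(sites = sites,
       peaks_a = mk(c("shared", "a_only"), config$conditions[1L]),
       peaks_b = mk(c("shared", "b_only"), config$conditions[2L]))
}

#' Simulate genome sequence with planted motif instances
#'
#' The genome is i.i.d. uniform A/C/G/T. For each binding site, each
#' applicable motif family is planted independently with probability
#' `motif_plant_prob`: the POU-like family at every site, the bZIP-like
#' family at `a_only` sites, and the HTH-like and bHLH-like families at
#' `b_only` sites in a repressed-to-active chromatin transition. A planted
#' consensus is centred on the site midpoint (offset 0); when two plants
#' collide at one midpoint the class-specific family keeps offset 0 (a fair
#' coin picks between HTH and bHLH) and the other is shifted by 16 bp.
#'
#' @param config a [simulation_config()].
#' @param sites site truth table from [simulate_peaks()].
#' @param seg_a,seg_b the two segmentations (for the repressed-to-active
#'   classification).
#' @return List with `genome` (named character vector) and `motif_truth`
#'   (`data.frame`: `site_id`, `motif_id`, `chrom`, `start`, `offset`).
#' @export
simulate_sequences_motifs <- function(config, sites, seg_a, seg_b) {
  set.seed(component_seed(config$seed, 40L))
  genome <- vapply(names(config$chrom_lengths), function(ch) {
    intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, config$chrom_lengths[[ch]],
                                               replace = TRUE)])
  }, "")
  cls <- transition_class(sites$class,
                          site_state(sites, seg_a),
                          site_state(sites, seg_b),
                          config$active_states)
  fams <- config$motif_families
  cons <- vapply(fams, pwm_consensus, "")
  mids <- interval_midpoint(sites$start, sites$end)
  p_site <- character(0); p_fam <- character(0); p_off <- integer(0)
  p_chrom <- character(0); p_mid <- integer(0)
  for (i in seq_len(nrow(sites))) {
    applicable <- "pou_like"
    if (sites$class[i] == "a_only") applicable <- c(applicable, "bzip_like")
    if (sites$class[i] == "b_only" && cls[i] == "repressed_to_active")
      applicable <- c(applicable, "hth_like", "bhlh_like")
    chosen <- applicable[stats::runif(length(applicable)) < config$motif_plant_prob]
    if (!length(chosen)) next
    class_fams <- setdiff(chosen, "pou_like")
    if (length(class_fams) == 2L && stats::runif(1L) < 0.5)
      class_fams <- rev(class_fams)
    fam_i <- character(0); off_i <- integer(0)
    if (length(class_fams) >= 1L) { fam_i <- class_fams[1L]; off_i <- 0L }
    if (length(class_fams) == 2L) {
      fam_i <- c(fam_i, class_fams[2L]); off_i <- c(off_i, 16L)
    }
    if ("pou_like" %in% chosen) {
      fam_i <- c(fam_i, "pou_like")
      off_i <- c(off_i, if (length(class_fams)) -16L else 0L)
    }
    p_site <- c(p_site, rep(sites$site_id[i], length(fam_i)))
    p_fam <- c(p_fam, fam_i); p_off <- c(p_off, off_i)
    p_chrom <- c(p_chrom, rep(sites$chrom[i], length(fam_i)))
    p_mid <- c(p_mid, rep(mids[i], length(fam_i)))
  }
  L <- nchar(cons)[p_fam]
  p_start <- p_mid + p_off - L %/% 2L          # 0-based start
  inside <- p_start >= 0L &
    p_start + L <= config$chrom_lengths[p_chrom]
  if (any(!inside))
    warning(sprintf("skipping %d motif plant(s) outside chromosome bounds",
                    sum(!inside)))
  motif_truth <- data.frame(site_id = p_site, motif_id = p_fam,
                            chrom = p_chrom, start = as.integer(p_start),
                            offset = p_off,
                            stringsAsFactors = FALSE)[inside, , drop = FALSE]
  rownames(motif_truth) <- NULL
  for (ch in unique(motif_truth$chrom)) {
    r <- charToRaw(genome[[ch]])
    sel <- which(motif_truth$chrom == ch)
    for (k in sel) {
      s0 <- motif_truth$start[k]
      cr <- charToRaw(cons[[motif_truth$motif_id[k]]])
      r[(s0 + 1L):(s0 + length(cr))] <- cr
    }
    genome[[ch]] <- rawToChar(r)
  }
  list(genome = genome, motif_truth = motif_truth)
}

#' Simulate a signal track of triangular bumps over peaks
#'
#' Each peak carries a symmetric triangular bump of height `signal_height`
#' above a flat baseline, discretised into `signal_step`-bp steps (step value
#' = triangle at the step midpoint, rounded to 4 decimals); the baseline
#' covers the rest of the genome.
#'
#' @param config a [simulation_config()].
#' @param peaks a [peak_set()].
#' @return A [signal_track()].
#' @export
simulate_signal_track <- function(config, peaks) {
  h <- config$signal_height; b <- config$signal_baseline
  stp <- config$signal_step
  rows <- list()
  for (ch in names(config$chrom_lengths)) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    cur <- 0L
    len <- config$chrom_lengths[[ch]]
    out <- list()
    for (i in seq_len(nrow(pk))) {
      if (pk$start[i] > cur)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur,
                                              end = pk$start[i], value = b)
      mid <- (pk$start[i] + pk$end[i]) / 2
      half <- (pk$end[i] - pk$start[i]) / 2
      ss <- seq(pk$start[i], pk$end[i] - 1L, by = stp)
      ee <- pmin(ss + stp, pk$end[i])
      v <- round(b + h * (1 - abs((ss + ee) / 2 - mid) / half), 4L)
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = ss, end = ee,
                                            value = v)
      cur <- pk$end[i]
    }
    if (cur < len)
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur,
                                            end = len, value = b)
    rows[[ch]] <- do.call(rbind, out)
  }
  signal_track(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Simulate a complete paired-condition dataset
#'
#' Orchestrates the component generators into one dataset with consistent
#' truth tables. Generation is a pure function of the configuration:
#' identical configs give byte-identical outputs when written with
#' [write_dataset()].
#'
#' @param config a [simulation_config()].
#' @param what character subset of
#'   `c("genes", "peaks", "sequences", "signal")` to generate beyond the
#'   segmentations and enhancer calls (all by default; trimming speeds up
#'   studies that only need part of the data).
#' @return List of class `"simulated_dataset"` with elements
#'   `config`, `segmentation` (per condition), `enhancers` (per condition),
#'   `genes`, `expr`, `sites`, `peaks` (per condition), `genome`,
#'   `tracks` (per condition), and `truth`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             what = c("genes", "peaks", "sequences", "signal")) {
  conds <- config$conditions
  seg <- lapply(stats::setNames(conds, conds), function(cc)
    simulate_segmentation(config, cc))
  enh <- lapply(stats::setNames(conds, conds), function(cc)
    call_enhancers(seg[[cc]], config$enhancer_states, config$max_gap,
                   config$stretch_min_bp, label = cc))
  out <- list(config = config, segmentation = seg, enhancers = enh,
              truth = list())
  if ("genes" %in% what) {
    ge <- simulate_genes_expression(
      config, enh[[conds[2L]]][enh[[conds[2L]]]$is_stretch, , drop = FALSE])
    out$genes <- ge$genes; out$expr <- ge$expr
    out$truth$bound_genes <- ge$truth$bound_genes
    out$truth$signature <- ge$truth$signature
  }
  if (any(c("peaks", "sequences", "signal") %in% what)) {
    pk <- simulate_peaks(config, seg[[1L]], seg[[2L]])
    out$sites <- pk$sites
    out$peaks <- stats::setNames(list(pk$peaks_a, pk$peaks_b), conds)
  }
  if ("sequences" %in% what) {
    sm <- simulate_sequences_motifs(config, out$sites, seg[[1L]], seg[[2L]])
    out$genome <- sm$genome
    out$truth$motifs <- sm$motif_truth
  }
  if ("signal" %in% what) {
    out$tracks <- lapply(out$peaks, function(p) simulate_signal_track(config, p))
  }
  class(out) <- "simulated_dataset"
  out
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated paired-condition dataset\n")
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb total\n",
              length(x$config$chrom_lengths),
              sum(x$config$chrom_lengths) / 1e6))
  for (cc in x$config$conditions)
    cat(sprintf("  %s: %d segments, %d enhancers (%d stretch)%s\n", cc,
                nrow(x$segmentation[[cc]]$segments), nrow(x$enhancers[[cc]]),
                sum(x$enhancers[[cc]]$is_stretch),
                if (!is.null(x$peaks)) sprintf(", %d peaks", nrow(x$peaks[[cc]])) else ""))
  if (!is.null(x$genes))
    cat(sprintf("  %d genes (%d bound, %d signature)\n", nrow(x$genes),
                length(x$truth$bound_genes), nrow(x$truth$signature)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the standard file dialects (segmentation BEDs, enhancer BED6s, peak
#' BEDs, gene TSV, expression TSV, genome FASTA, bedGraphs) plus
#' `truth/*.tsv` tables of the planted structure.
#'
#' @param ds a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(ds, outdir) {
  dir.create(file.path(outdir, "truth"), recursive = TRUE, showWarnings = FALSE)
  conds <- ds$config$conditions
  for (cc in conds) {
    write_segmentation(ds$segmentation[[cc]],
                       file.path(outdir, paste0("segmentation_", cc, ".bed")))
    e <- ds$enhancers[[cc]]
    write_bed(data.frame(chrom = e$chrom, start = e$start, end = e$end,
                         name = ifelse(e$is_stretch, "stretch", "typical"),
                         stringsAsFactors = FALSE),
              file.path(outdir, paste0("enhancers_", cc, ".bed")))
    if (!is.null(ds$peaks))
      write_bed(as.data.frame(ds$peaks[[cc]]),
                file.path(outdir, paste0("peaks_", cc, ".bed")))
    if (!is.null(ds$tracks))
      write_bedgraph(ds$tracks[[cc]],
                     file.path(outdir, paste0("signal_", cc, ".bedgraph")))
  }
  if (!is.null(ds$genes)) {
    write_gene_table(ds$genes, file.path(outdir, "genes.tsv"))
    write_expression(ds$expr, file.path(outdir, "expression.tsv"))
    write_lf(c("gene_id", ds$truth$bound_genes),
             file.path(outdir, "truth", "bound_genes.tsv"))
    sig <- ds$truth$signature
    write_lf(c("gene_id\tenh_chrom\tenh_start\tenh_end",
               if (nrow(sig)) paste(sig$gene_id, sig$enh_chrom, sig$enh_start,
                                    sig$enh_end, sep = "\t")),
             file.path(outdir, "truth", "signature_genes.tsv"))
  }
  if (!is.null(ds$sites))
    write_lf(c("site_id\tchrom\tstart\tend\tclass",
               paste(ds$sites$site_id, ds$sites$chrom, ds$sites$start,
                     ds$sites$end, ds$sites$class, sep = "\t")),
             file.path(outdir, "truth", "sites.tsv"))
  if (!is.null(ds$genome))
    write_fasta(ds$genome, file.path(outdir, "genome.fa"))
  if (!is.null(ds$truth$motifs)) {
    m <- ds$truth$motifs
    write_lf(c("site_id\tmotif_id\tchrom\tstart\toffset",
               if (nrow(m)) paste(m$site_id, m$motif_id, m$chrom, m$start,
                                  m$offset, sep = "\t")),
             file.path(outdir, "truth", "motifs.tsv"))
  }
  invisible(outdir)
}
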