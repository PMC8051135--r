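## Brute-force oracles, deliberately independent of the package's
## implementations: per-base occupancy arrays, all-pairs scans, exhaustive
## enumeration. Slow by construction; used on small random instances.

# merge via a per-bp boolean occupancy array, closing gaps <= max_gap
oracle_merge <- function(intervals, max_gap) {
  out <- list()
  for (ch in sort(unique(intervals$chrom))) {
    x <- intervals[intervals$chrom == ch, , drop = FALSE]
    n <- max(x$end)
    occ <- logical(n)
    for (i in seq_len(nrow(x))) occ[(x$start[i] + 1):x$end[i]] <- TRUE
    # close gaps of length <= max_gap between covered runs
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] && k > 1 && k < length(r$values) &&
          r$lengths[k] <= max_gap)
        occ[starts[k]:ends[k]] <- TRUE
    }
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep))
      out[[ch]] <- data.frame(chrom = ch, start = as.integer(starts[keep] - 1),
                              end = as.integer(ends[keep]),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

random_intervals <- function(n, chroms = c("chr1", "chr2", "chr3"),
                             max_pos = 5000, max_len = 200) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# point-to-interval distance, scalar, written from the definition
oracle_point_dist <- function(start, end, pos) {
  if (pos >= start && pos < end) return(0)
  min(abs(pos - start), abs(pos - (end - 1)))
}

# all-pairs TSS proximity
oracle_tss_proximal <- function(peaks, genes, max_dist) {
  vapply(seq_len(nrow(peaks)), function(i) {
    d <- Inf
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      d <- min(d, oracle_point_dist(peaks$start[i], peaks$end[i], genes$tss[j]))
    }
    d <= max_dist
  }, TRUE)
}

# all-pairs distinct proximal enhancer count
oracle_count_proximal <- function(genes, enh, half_window) {
  hit <- logical(nrow(enh))
  for (i in seq_len(nrow(enh))) {
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != enh$chrom[i]) next
      if (oracle_point_dist(enh$start[i], enh$end[i], genes$tss[j]) <= half_window)
        hit[i] <- TRUE
    }
  }
  sum(hit)
}

# all-pairs bidirectional sharing labels
oracle_sharing <- function(a, b, f) {
  lab_a <- logical(nrow(a)); lab_b <- logical(nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov > 0 && ov >= f * (a$end[i] - a$start[i]) &&
        ov >= f * (b$end[j] - b$start[j])) {
      lab_a[i] <- TRUE; lab_b[j] <- TRUE
    }
  }
  list(shared_a = lab_a, shared_b = lab_b)
}

random_pwm <- function(len, concentration = 1) {
  m <- matrix(stats::rgamma(4 * len, concentration), 4, len)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  chromstretch::pwm(m)
}

# exhaustive min/max log2-odds over all 4^L sequences
oracle_pwm_bounds <- function(p) {
  L <- ncol(p$matrix)
  w <- log2(p$matrix / p$background)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(grid))
  for (j in 1:L) scores <- scores + w[grid[, j] + (j - 1) * 4]
  c(min(scores), max(scores))
}

# direct per-window scoring on both strands; threshold from exhaustive bounds
oracle_scan <- function(seq, p, rel_threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- ncol(p$matrix)
  w <- log2(p$matrix / p$background)
  b <- oracle_pwm_bounds(p)
  thr <- b[1] + rel_threshold * (b[2] - b[1])
  chars <- strsplit(seq, "")[[1]]
  hits <- NULL
  for (s in seq_len(length(chars) - L + 1)) {
    win <- chars[s:(s + L - 1)]
    if (any(!win %in% names(comp))) next
    fwd <- sum(vapply(1:L, function(j) w[win[j], j], 0))
    rcw <- rev(unname(comp[win]))
    rev_ <- sum(vapply(1:L, function(j) w[rcw[j], j], 0))
    if (fwd >= thr - 1e-9)
      hits <- rbind(hits, data.frame(start = s - 1, strand = "+", score = fwd))
    if (rev_ >= thr - 1e-9)
      hits <- rbind(hits, data.frame(start = s - 1, strand = "-", score = rev_))
  }
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exact two-sided Mann-Whitney p by enumerating every group assignment
oracle_mw_exact <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(pool), n1)
  u_all <- apply(combos, 2, function(ix) u_of(pool[ix], pool[-ix]))
  center <- n1 * (length(pool) - n1) / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}
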