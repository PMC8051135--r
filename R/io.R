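## Readers and writers for the plain-text dialects the pipeline touches.
## Writers are byte-stable: tab separators, LF line endings, no trailing
## whitespace, records sorted — so equal objects give identical files.

num2str <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

write_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_table_lines <- function(path, n_fields, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_fields)
  if (length(bad))
    stop(sprintf("%s: malformed %s line(s): %s (expected >= %d tab-separated fields)",
                 path, what, paste(utils::head(bad, 5L), collapse = ", "), n_fields))
  fields
}

#' Read / write BED intervals
#'
#' BED3 (`chrom start end`) or BED6 (`+ name score strand`), tab-separated,
#' no header. Coordinates are validated (`0 <= start < end`), with offending
#' line numbers reported.
#'
#' @param path file path.
#' @return `read_bed()`: a `data.frame` with columns `chrom`, `start`, `end`
#'   and, for BED6 input, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  fields <- read_table_lines(path, 3L, "BED")
  if (length(fields) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  x <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                  start = as.integer(vapply(fields, `[`, "", 2L)),
                  end = as.integer(vapply(fields, `[`, "", 3L)),
                  stringsAsFactors = FALSE)
  if (all(lengths(fields) >= 6L)) {
    x$name <- vapply(fields, `[`, "", 4L)
    x$score <- as.numeric(vapply(fields, `[`, "", 5L))
    x$strand <- vapply(fields, `[`, "", 6L)
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(sprintf("%s: invalid BED coordinates at line(s) %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  x
}

#' @rdname read_bed
#' @param x interval `data.frame`; written as BED6 when `name` is present
#'   (missing `score` -> 0, missing `strand` -> `"."`), BED3 otherwise.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  if (!is.null(x$name)) {
    score <- if (is.null(x$score)) rep(0, nrow(x)) else x$score
    strand <- if (is.null(x$strand)) rep(".", nrow(x)) else x$strand
    lines <- paste(x$chrom, x$start, x$end, x$name, num2str(score), strand,
                   sep = "\t")
  } else {
    lines <- paste(x$chrom, x$start, x$end, sep = "\t")
  }
  write_lf(lines, path)
}

#' Read / write a chromatin-state segmentation BED
#'
#' Four-column BED whose 4th column is a state label `E<k>` (ChromHMM
#' `*_segments.bed` style); `"E7"` maps to integer state 7. Unsorted or
#' overlapping segments and unknown labels are errors reporting line numbers.
#'
#' @param path file path.
#' @param state_count number of states in the model.
#' @param resolution informational bin size (bp).
#' @return `read_segmentation()`: a [segmentation()].
#' @export
read_segmentation <- function(path, state_count = 11L, resolution = 200L) {
  fields <- read_table_lines(path, 4L, "segmentation")
  if (length(fields) == 0L)
    return(segmentation(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), state = integer(0)),
                        state_count, resolution))
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.integer(vapply(fields, `[`, "", 2L))
  end <- as.integer(vapply(fields, `[`, "", 3L))
  lab <- vapply(fields, `[`, "", 4L)
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("%s: invalid coordinates at line(s) %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  state <- suppressWarnings(as.integer(sub("^E", "", lab)))
  bad <- which(!grepl("^E[0-9]+$", lab) | is.na(state) |
                 state < 1L | state > state_count)
  if (length(bad))
    stop(sprintf("%s: unknown state label at line(s) %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  o <- order(chrom, start)
  if (any(o != seq_along(o)))
    stop(sprintf("%s: segmentation not sorted; offending line(s) %s", path,
                 paste(utils::head(which(o != seq_along(o)), 5L), collapse = ", ")))
  segmentation(data.frame(chrom = chrom, start = start, end = end,
                          state = state, stringsAsFactors = FALSE),
               state_count, resolution)
}

#' @rdname read_segmentation
#' @param seg a [segmentation()].
#' @export
write_segmentation <- function(seg, path) {
  s <- seg$segments
  write_lf(paste(s$chrom, s$start, s$end, paste0("E", s$state), sep = "\t"),
           path)
}

#' Read / write the gene annotation table
#'
#' Tab-separated with header `gene_id chrom strand tss`.
#'
#' @param path file path.
#' @return `read_gene_table()`: a [gene_table()].
#' @export
read_gene_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_table(x)
}

#' @rdname read_gene_table
#' @param genes a [gene_table()].
#' @export
write_gene_table <- function(genes, path) {
  lines <- c("gene_id\tchrom\tstrand\ttss",
             paste(genes$gene_id, genes$chrom, genes$strand, genes$tss,
                   sep = "\t"))
  write_lf(lines, path)
}

#' Read / write the expression matrix
#'
#' Tab-separated with header `gene_id <condition> ...`; FPKM values must be
#' non-negative.
#'
#' @param path file path.
#' @return `read_expression()`: an [expression_matrix()].
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  expression_matrix(x)
}

#' @rdname read_expression
#' @param expr an [expression_matrix()].
#' @export
write_expression <- function(expr, path) {
  conds <- attr(expr, "conditions")
  body <- expr$gene_id
  for (cc in conds) body <- paste(body, num2str(expr[[cc]]), sep = "\t")
  write_lf(c(paste(c("gene_id", conds), collapse = "\t"), body), path)
}

#' Read / write JASPAR position frequency matrices
#'
#' JASPAR 2016+ text format: a `>ID name` header followed by four rows
#' `A [ 10 3 ... ]` (then C, G, T). `read_jaspar_pfm()` returns raw count
#' matrices; convert to probability PWMs with [as_pwm()].
#'
#' @param path file path.
#' @return `read_jaspar_pfm()`: named list of 4 x L count matrices
#'   (rows A, C, G, T), with attribute `"name"` per matrix.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop(sprintf("%s: no '>' motif header found", path))
  out <- list()
  for (k in seq_along(heads)) {
    i <- heads[k]
    if (i + 4L > length(lines))
      stop(sprintf("%s: truncated motif record at line %d", path, i))
    hdr <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]]
    rows <- lines[(i + 1L):(i + 4L)]
    base <- sub("^\\s*([ACGT]).*$", "\\1", rows)
    if (!identical(base, c("A", "C", "G", "T")))
      stop(sprintf("%s: motif at line %d must have rows A, C, G, T", path, i))
    vals <- lapply(rows, function(r) {
      as.numeric(strsplit(trimws(gsub("^[^\\[]*\\[|\\].*$", "", r)), "\\s+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1L)
      stop(sprintf("%s: ragged motif rows at line %d", path, i))
    m <- do.call(rbind, vals)
    rownames(m) <- c("A", "C", "G", "T")
    attr(m, "name") <- if (length(hdr) > 1L) hdr[2L] else hdr[1L]
    out[[hdr[1L]]] <- m
  }
  out
}

#' @rdname read_jaspar_pfm
#' @param pfms named list of 4 x L count matrices.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  lines <- character(0)
  for (id in names(pfms)) {
    m <- pfms[[id]]
    nm <- attr(m, "name")
    lines <- c(lines,
               paste0(">", id, if (!is.null(nm) && !identical(nm, id)) paste0(" ", nm)),
               vapply(c("A", "C", "G", "T"), function(b)
                 paste0(b, " [ ", paste(num2str(m[b, ]), collapse = " "), " ]"),
                 ""))
  }
  write_lf(lines, path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings that return/accept plain named character
#' vectors (one element per chromosome).
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  lines <- character(0)
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    lines <- c(lines, paste0(">", nm),
               substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  write_lf(lines, path)
}

#' Read / write bedGraph signal tracks
#'
#' @param path file path.
#' @return `read_bedgraph()`: a [signal_track()].
#' @export
read_bedgraph <- function(path) {
  fields <- read_table_lines(path, 4L, "bedGraph")
  x <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                  start = as.integer(vapply(fields, `[`, "", 2L)),
                  end = as.integer(vapply(fields, `[`, "", 3L)),
                  value = as.numeric(vapply(fields, `[`, "", 4L)),
                  stringsAsFactors = FALSE)
  bad <- which(is.na(x$start) | is.na(x$end) | is.na(x$value) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(sprintf("%s: invalid bedGraph line(s) %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  signal_track(x)
}

#' @rdname read_bedgraph
#' @param track a [signal_track()].
#' @export
write_bedgraph <- function(track, path) {
  write_lf(paste(track$chrom, track$start, track$end, num2str(track$value),
                 sep = "\t"), path)
}
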