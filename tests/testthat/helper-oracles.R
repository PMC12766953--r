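# Independent oracles used to verify the implementation. These deliberately
# share no code with the package internals: their own reverse complement,
# their own scoring arithmetic straight from the count matrix, and naive
# all-pairs interval overlap.

# the 2-position toy count matrix used throughout the scoring tests:
# position 1 favours A (3) over C (1); position 2 favours G (3) over T (1)
toy_counts <- function() {
  matrix(c(3, 1, 0, 0,
           0, 0, 3, 1), nrow = 4,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# per-cell log2-odds scores evaluated directly from counts
oracle_cells <- function(counts, pseudocount = 1, background = rep(0.25, 4)) {
  shifted <- counts + pseudocount
  log2(t(t(shifted) / colSums(shifted)) / background)
}

oracle_absolute <- function(counts, window, pseudocount = 1,
                            background = rep(0.25, 4)) {
  cells <- oracle_cells(counts, pseudocount, background)
  idx <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  sum(cells[cbind(idx, seq_along(idx))])
}

oracle_rel <- function(counts, window, pseudocount = 1,
                       background = rep(0.25, 4)) {
  cells <- oracle_cells(counts, pseudocount, background)
  a <- oracle_absolute(counts, window, pseudocount, background)
  (a - sum(apply(cells, 2, min))) /
    (sum(apply(cells, 2, max)) - sum(apply(cells, 2, min)))
}

# exhaustive enumeration of every window on both strands, scored straight
# from the count matrix; mirrors the scan contract's output columns
oracle_scan <- function(counts, sequence, threshold, strands = "both") {
  W <- ncol(counts)
  L <- nchar(sequence)
  rows <- list()
  if (L >= W) {
    for (o in 0:(L - W)) {
      fwd <- substr(sequence, o + 1, o + W)
      a <- oracle_absolute(counts, fwd)
      if (!is.na(a)) {
        r <- oracle_rel(counts, fwd)
        if (r >= threshold)
          rows[[length(rows) + 1]] <-
            data.frame(offset = o, strand = "+", matched = fwd,
                       absolute = a, relative = r, stringsAsFactors = FALSE)
      }
      if (strands == "both") {
        rev <- oracle_revcomp(fwd)
        a <- oracle_absolute(counts, rev)
        if (!is.na(a)) {
          r <- oracle_rel(counts, rev)
          if (r >= threshold)
            rows[[length(rows) + 1]] <-
              data.frame(offset = o, strand = "-", matched = rev,
                         absolute = a, relative = r,
                         stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(offset = integer(0), strand = character(0),
               matched = character(0), absolute = numeric(0),
               relative = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$offset, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive all-pairs interval overlap (half-open), the oracle for
# intersect_intervals
brute_overlap <- function(a, b) {
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$contig[i] != b$contig[j]) next
    s <- max(a$start[i], b$start[j])
    e <- min(a$end[i], b$end[j])
    if (e - s >= 1)
      rows[[length(rows) + 1]] <-
        data.frame(a_index = i, b_index = j, contig = a$contig[i],
                   start = s, end = e, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(a_index = integer(0), b_index = integer(0),
               contig = character(0), start = numeric(0), end = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start, out$a_index, out$b_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, contigs = c("c1", "c2", "c3"),
                             max_pos = 1000) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1
  w <- sample.int(50, n, replace = TRUE)
  genomic_intervals(sample(contigs, n, replace = TRUE), s, s + w)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random non-degenerate PFM for oracle-equivalence sweeps
random_pfm <- function(width) {
  repeat {
    counts <- matrix(sample(0:9, 4 * width, replace = TRUE), nrow = 4,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    cells <- oracle_cells(counts)
    if (sum(apply(cells, 2, max)) - sum(apply(cells, 2, min)) > 1e-9)
      return(counts)
  }
}
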