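#' Build a log2-odds scoring matrix from a position frequency matrix
#'
#' Converts per-position nucleotide counts into a position-specific scoring
#' matrix (PSSM). A pseudocount is first added to every count so no
#' frequency is zero; counts are then renormalized per column into observed
#' frequencies, and each cell scored as
#' `log2(observed / background)` — the log2 odds ratio of observed over
#' expected frequency. The matrix's attainable score range
#' (`min_score` = sum of column minima, `max_score` = sum of column maxima)
#' is derived at the same time and drives [relative_score()].
#'
#' A profile where every column is uniform after pseudocounting has
#' `max_score == min_score`; the relative score is then undefined and a
#' `degenerate_profile` error is raised.
#'
#' @param pfm A `jaspar_pfm` object (see [read_jaspar_pfm()]), or a 4 x
#'   width count matrix with rownames `A`, `C`, `G`, `T`.
#' @param pseudocount Non-negative value added to every count (default 1).
#'   Must be positive unless every count already is.
#' @param background Background base probabilities in A, C, G, T order;
#'   default uniform 0.25. Must be strictly positive and sum to 1.
#' @return A list of class `pssm`: `width`, `scores` (4 x width matrix),
#'   `min_score`, `max_score`, `background`, `pseudocount`, plus the source
#'   motif id/name when available.
#' @examples
#' counts <- matrix(c(3, 1, 0, 0, 0, 0, 3, 1), nrow = 4,
#'                  dimnames = list(c("A", "C", "G", "T"), NULL))
#' pssm <- pfm_to_pssm(counts)
#' pssm$scores       # position 1: A=1, C=0, G=-1, T=-1
#' pssm$max_score    # 2
#' @export
pfm_to_pssm <- function(pfm, pseudocount = 1,
                        background = rep(0.25, 4)) {
  counts <- if (inherits(pfm, "jaspar_pfm")) pfm$counts else pfm
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(counts < 0)) stop("negative count in PFM")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount == 0 && any(counts == 0))
    stop("pseudocount must be positive when the PFM contains zero counts")
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 strictly positive probabilities")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background probabilities must sum to 1")
  shifted <- counts + pseudocount
  observed <- sweep(shifted, 2L, colSums(shifted), "/")
  scores <- log2(observed / background)
  min_score <- sum(apply(scores, 2L, min))
  max_score <- sum(apply(scores, 2L, max))
  if (max_score - min_score <= 1e-12)
    stop(degenerate_profile_error())
  structure(list(
    width = ncol(scores),
    scores = scores,
    min_score = min_score,
    max_score = max_score,
    background = as.numeric(background),
    pseudocount = pseudocount,
    motif_id = if (inherits(pfm, "jaspar_pfm")) pfm$motif_id else NA_character_,
    motif_name = if (inherits(pfm, "jaspar_pfm")) pfm$motif_name
                 else NA_character_
  ), class = "pssm")
}

degenerate_profile_error <- function() {
  structure(class = c("degenerate_profile", "error", "condition"),
            list(message = paste("degenerate profile: max_score equals",
                                 "min_score, relative score undefined"),
                 call = sys.call(-1L)))
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM", if (!is.na(x$motif_id)) x$motif_id else "", "- width",
      x$width, "\n")
  cat(sprintf("score range [%.4f, %.4f], pseudocount %g\n",
              x$min_score, x$max_score, x$pseudocount))
  print(round(x$scores, 4L))
  invisible(x)
}

base_index <- function(sequence) {
  # A=1 C=2 G=3 T=4, NA for anything else (N etc.)
  match(strsplit(sequence, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
}

#' Score one window against a PSSM
#'
#' Sums the per-position log2-odds scores of a window whose length equals
#' the matrix width. A window containing any character outside
#' `{A,C,G,T}` is not scorable and yields `NA`.
#'
#' @param pssm A `pssm` object (see [pfm_to_pssm()]).
#' @param window Nucleotide string of length `pssm$width`.
#' @return The absolute (log2-odds sum) score, or `NA` if not scorable.
#' @export
score_window <- function(pssm, window) {
  if (nchar(window) != pssm$width)
    stop("window length ", nchar(window), " != matrix width ", pssm$width)
  idx <- base_index(window)
  if (anyNA(idx)) return(NA_real_)
  sum(pssm$scores[cbind(idx, seq_along(idx))])
}

#' Relative score of an absolute PSSM score
#'
#' Rescales an absolute score into `[0, 1]` between the matrix's attainable
#' minimum and maximum: `(absolute - min_score) / (max_score - min_score)`.
#' For pseudocounted log2-odds matrices `min_score <= 0 <= max_score`
#' always holds, in which case this equals the form
#' `(absolute + |minScore|) / (|maxScore| + |minScore|)`. The result is
#' clamped to `[0, 1]` only against floating-point drift (up to 1e-12).
#'
#' @param pssm A `pssm` object.
#' @param absolute Absolute score(s) as returned by [score_window()].
#' @return Relative score(s) in `[0, 1]`; `NA` passes through.
#' @export
relative_score <- function(pssm, absolute) {
  span <- pssm$max_score - pssm$min_score
  if (span <= 1e-12) stop(degenerate_profile_error())
  rel <- (absolute - pssm$min_score) / span
  pmin(1, pmax(0, rel)) * ifelse(is.na(rel), NA_real_, 1)
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence Character vector of uppercase strings over
#'   `{A,C,G,T,N}`; anything else is an error.
#' @return The reverse-complemented string(s). Applying twice is the
#'   identity.
#' @examples
#' reverse_complement("CGTA")  # "TACG"
#' @export
reverse_complement <- function(sequence) {
  if (any(grepl("[^ACGTN]", sequence)))
    stop("reverse_complement: sequence contains characters outside ACGTN")
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
  names(out) <- names(sequence)
  if (length(out) == 1L) out <- unname(out)
  out
}

#' Scan a sequence with a PSSM on one or both strands
#'
#' Slides a window of the matrix width over the sequence. At each offset the
#' forward window is scored and, when `strands = "both"`, the reverse
#' complement of the same genomic window is scored as a `-` strand
#' candidate. Windows whose relative score reaches `threshold` are
#' retained; windows containing non-ACGT characters are skipped and counted
#' in the `n_not_scorable` attribute. All qualifying windows are reported —
#' overlapping hits are not masked.
#'
#' @param pssm A `pssm` object.
#' @param sequence Uppercase nucleotide string (the `+` strand of the
#'   region being scanned).
#' @param threshold Minimum relative score to retain, in `[0, 1]`
#'   (default 0.8; a site scoring exactly the threshold is kept).
#' @param strands `"both"` (default) or `"plus_only"`.
#' @return A `data.frame` with columns `offset` (0-based window start
#'   within `sequence`), `strand` (`"+"`/`"-"` on the genome), `matched`
#'   (the strand-adjusted window string), `absolute`, `relative`; sorted by
#'   `(offset, strand)` with `+` before `-`. Attribute `n_not_scorable`
#'   counts skipped windows.
#' @export
scan_sequence <- function(pssm, sequence, threshold = 0.8,
                          strands = c("both", "plus_only")) {
  strands <- match.arg(strands)
  if (threshold < 0 || threshold > 1)
    stop("threshold must be within [0, 1]")
  W <- pssm$width
  L <- nchar(sequence)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      matched = character(0), absolute = numeric(0),
                      relative = numeric(0), stringsAsFactors = FALSE)
  attr(empty, "n_not_scorable") <- 0L
  if (L < W) return(empty)

  scan_one <- function(seq_str) {
    idx <- base_index(seq_str)
    n_win <- L - W + 1L
    acc <- numeric(n_win)
    for (p in seq_len(W))
      acc <- acc + pssm$scores[cbind(idx[p:(n_win + p - 1L)], p)]
    acc
  }

  abs_fwd <- scan_one(sequence)
  offs <- seq_len(length(abs_fwd)) - 1L
  res <- data.frame(offset = offs, strand = "+", absolute = abs_fwd,
                    stringsAsFactors = FALSE)
  res$matched <- substring(sequence, offs + 1L, offs + W)
  n_skip <- sum(is.na(abs_fwd))

  if (strands == "both") {
    seq_clean <- gsub("[^ACGTN]", "N", sequence)
    rc <- reverse_complement(seq_clean)
    abs_rev <- scan_one(rc)
    offs_rc <- seq_len(length(abs_rev)) - 1L
    rev_df <- data.frame(offset = L - W - offs_rc, strand = "-",
                         absolute = abs_rev, stringsAsFactors = FALSE)
    rev_df$matched <- substring(rc, offs_rc + 1L, offs_rc + W)
    n_skip <- n_skip + sum(is.na(abs_rev))
    res <- rbind(res, rev_df)
  }

  res <- res[!is.na(res$absolute), , drop = FALSE]
  res$relative <- relative_score(pssm, res$absolute)
  res <- res[res$relative >= threshold, , drop = FALSE]
  res <- res[order(res$offset, match(res$strand, c("+", "-"))), ,
             drop = FALSE]
  res <- res[, c("offset", "strand", "matched", "absolute", "relative")]
  rownames(res) <- NULL
  attr(res, "n_not_scorable") <- n_skip
  res
}
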