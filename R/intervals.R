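#' Construct a table of genomic intervals
#'
#' The package represents genomic intervals as a plain `data.frame` with
#' columns `contig`, `start`, `end`, `name`, `strand`, `label`. Coordinates
#' are 0-based half-open (`[start, end)`), the BED convention, everywhere in
#' the package. `strand` is `"+"`, `"-"`, or `"."` (unstranded); `name` and
#' `label` are optional annotations (`NA` when absent).
#'
#' @param contig Character vector of contig names (non-empty strings).
#' @param start Integer-valued vector of 0-based inclusive start positions.
#' @param end Integer-valued vector of 0-based exclusive end positions.
#' @param name Optional character vector of interval names.
#' @param strand Strand per interval: `"+"`, `"-"` or `"."` (default).
#' @param label Optional character vector of annotation labels (e.g. a cCRE
#'   class such as `"PLS"` or `"dELS"`).
#' @return A `data.frame` with one row per interval and the six columns
#'   above.
#' @examples
#' genomic_intervals("chr1", 100, 200, name = "peak1", strand = "+")
#' @export
genomic_intervals <- function(contig, start, end, name = NA_character_,
                              strand = ".", label = NA_character_) {
  n <- max(length(contig), length(start), length(end))
  gi <- data.frame(
    contig = rep_len(as.character(contig), n),
    start  = rep_len(as.numeric(start), n),
    end    = rep_len(as.numeric(end), n),
    name   = rep_len(as.character(name), n),
    strand = rep_len(as.character(strand), n),
    label  = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(gi)
  gi
}

validate_intervals <- function(gi) {
  stopifnot(is.data.frame(gi))
  required <- c("contig", "start", "end")
  missing <- setdiff(required, names(gi))
  if (length(missing) > 0L)
    stop("interval table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(gi) == 0L) return(invisible(gi))
  if (any(is.na(gi$contig) | !nzchar(gi$contig)))
    stop("interval with empty contig name")
  if (any(gi$start != trunc(gi$start)) || any(gi$end != trunc(gi$end)))
    stop("non-integer interval coordinate")
  bad <- gi$start < 0 | gi$start >= gi$end
  if (any(bad))
    stop("invalid interval (need 0 <= start < end) at row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  if (!is.null(gi$strand) && !all(gi$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(gi)
}

# empty interval table with the canonical columns
empty_intervals <- function() {
  genomic_intervals(character(0), numeric(0), numeric(0))
}

# locale-independent lexicographic label sort (case-insensitive first key,
# so "dELS" < "PLS" everywhere)
sort_labels <- function(x) x[order(tolower(x), x, method = "radix")]

as_granges <- function(gi, seqlevels = unique(gi$contig)) {
  # internal bridge to GenomicRanges; shifts 0-based half-open to 1-based
  # closed as GRanges expects
  GenomicRanges::GRanges(
    seqnames = factor(gi$contig, levels = seqlevels),
    ranges = IRanges::IRanges(start = gi$start + 1L, end = gi$end)
  )
}

#' Intersect two interval sets
#'
#' Reports every pair of intervals (one from `a`, one from `b`) on the same
#' contig whose half-open spans overlap by at least `min_overlap` base
#' pairs, together with the overlap segment `(max(starts), min(ends))`.
#' Touching intervals (`end == start`) do not overlap. The overlap search is
#' delegated to [GenomicRanges::findOverlaps()].
#'
#' @param a,b Interval tables as produced by [genomic_intervals()].
#' @param min_overlap Minimum overlap in bp to report a pair (default 1).
#' @return A `data.frame` with columns `a_index`, `b_index`, `contig`,
#'   `start`, `end` (the overlap segment), sorted by
#'   `(contig, start, a_index, b_index)`.
#' @examples
#' a <- genomic_intervals("c1", 100, 200)
#' b <- genomic_intervals("c1", 150, 250)
#' intersect_intervals(a, b)
#' @export
intersect_intervals <- function(a, b, min_overlap = 1L) {
  validate_intervals(a)
  validate_intervals(b)
  out <- data.frame(a_index = integer(0), b_index = integer(0),
                    contig = character(0), start = numeric(0),
                    end = numeric(0), stringsAsFactors = FALSE)
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  lv <- unique(c(a$contig, b$contig))
  hits <- GenomicRanges::findOverlaps(as_granges(a, lv), as_granges(b, lv),
                                      minoverlap = as.integer(min_overlap))
  if (length(hits) == 0L) return(out)
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    a_index = ai,
    b_index = bi,
    contig = a$contig[ai],
    start = pmax(a$start[ai], b$start[bi]),
    end = pmin(a$end[ai], b$end[bi]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$start, out$a_index, out$b_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a transcript table
#'
#' Transcripts are stranded genomic intervals carrying a RefSeq-style
#' accession and a gene symbol. The transcription start site (TSS) is the
#' `start` coordinate for `+` transcripts and the `end` coordinate for `-`
#' transcripts.
#'
#' @param accession Character vector of transcript accessions.
#' @param contig,start,end,strand Interval fields; `strand` must be `"+"` or
#'   `"-"` for every transcript (the TSS is undefined otherwise).
#' @param gene Gene symbols; defaults to the accession.
#' @return A `data.frame` with columns `accession`, `contig`, `start`,
#'   `end`, `strand`, `gene`.
#' @examples
#' transcripts("NM_001", "chr1", 10000, 12000, "+", gene = "Nlrp3")
#' @export
transcripts <- function(accession, contig, start, end, strand,
                        gene = accession) {
  tx <- data.frame(
    accession = as.character(accession),
    contig = as.character(contig),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    gene = as.character(gene),
    stringsAsFactors = FALSE
  )
  validate_intervals(tx)
  if (!all(tx$strand %in% c("+", "-")))
    stop("transcript strand must be '+' or '-' (TSS undefined otherwise)")
  tx
}

#' Transcripts from a BED-derived interval table
#'
#' Interprets the BED `name` column as the transcript accession. Gene
#' symbols default to the accession; supply `genes` to override (recycled
#' against the rows).
#'
#' @param gi Interval table, typically from [read_bed()] with
#'   `min_columns = 6` so the strand is present.
#' @param genes Gene symbols, defaulting to the interval names.
#' @return A transcript table, see [transcripts()].
#' @export
transcripts_from_bed <- function(gi, genes = gi$name) {
  transcripts(gi$name, gi$contig, gi$start, gi$end, gi$strand, gene = genes)
}

#' Extend a transcript upstream of its TSS
#'
#' Builds the search window for a transcript: the transcript body plus
#' `upstream_bp` bases upstream of the transcription start site. For a `+`
#' transcript the window is `(start - upstream_bp, end)`; for a `-`
#' transcript `(start, end + upstream_bp)`. The window is clamped to
#' `[0, contig_length)`.
#'
#' @param tx A one-row transcript table (see [transcripts()]).
#' @param upstream_bp Non-negative extension in bp (default 5000).
#' @param contig_length Length of the transcript's contig, for clamping; use
#'   `Inf` to skip end clamping.
#' @return A one-row interval table carrying the transcript's strand (in
#'   `strand`) and gene symbol (in `name`).
#' @examples
#' tx <- transcripts("NM_1", "chr1", 10000, 12000, "+", gene = "g")
#' extend_upstream(tx, 5000, contig_length = 2e6)
#' @export
extend_upstream <- function(tx, upstream_bp = 5000L, contig_length = Inf) {
  stopifnot(nrow(tx) == 1L, upstream_bp >= 0)
  if (!tx$strand %in% c("+", "-"))
    stop("unstranded transcript: TSS undefined")
  if (tx$strand == "+") {
    s <- max(0, tx$start - upstream_bp)
    e <- min(contig_length, tx$end)
  } else {
    s <- max(0, tx$start)
    e <- min(contig_length, tx$end + upstream_bp)
  }
  genomic_intervals(tx$contig, s, e, name = tx$gene, strand = tx$strand)
}

#' Build search regions from transcripts and per-TF peaks
#'
#' For every transcript, extends its window `upstream_bp` bp upstream of the
#' TSS and intersects the window with each transcription factor's peak set.
#' One search region is emitted per overlapping peak, carrying the clipped
#' peak-window overlap segment (or, with `clip_to_window = FALSE`, the whole
#' peak). Regions identical in (gene, tf, contig, start, end) are collapsed.
#'
#' @param tx Transcript table ([transcripts()]).
#' @param peaks_by_tf Named list mapping a transcription-factor label to an
#'   interval table of its ChIP-seq peaks.
#' @param upstream_bp Upstream extension in bp (default 5000).
#' @param contig_lengths Named numeric vector of contig lengths used to
#'   clamp windows; missing contigs are treated as unbounded.
#' @param clip_to_window Scan only the peak-window overlap (default `TRUE`)
#'   rather than the full peak.
#' @param min_overlap Minimum peak-window overlap in bp (default 1).
#' @return A `data.frame` with columns `gene`, `tf`, `contig`, `start`,
#'   `end`, `tx_strand`, `source_transcript`, `source_peak`.
#' @export
build_search_regions <- function(tx, peaks_by_tf, upstream_bp = 5000L,
                                 contig_lengths = NULL,
                                 clip_to_window = TRUE, min_overlap = 1L) {
  stopifnot(is.list(peaks_by_tf))
  if (length(peaks_by_tf) > 0L &&
      (is.null(names(peaks_by_tf)) || any(!nzchar(names(peaks_by_tf)))))
    stop("peaks_by_tf must be a named list (TF label -> peak table)")
  windows <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    len <- if (!is.null(contig_lengths) &&
               tx$contig[i] %in% names(contig_lengths))
      contig_lengths[[tx$contig[i]]] else Inf
    extend_upstream(tx[i, , drop = FALSE], upstream_bp, contig_length = len)
  }))
  out <- list()
  for (tf in names(peaks_by_tf)) {
    peaks <- peaks_by_tf[[tf]]
    ov <- intersect_intervals(windows, peaks, min_overlap = min_overlap)
    if (nrow(ov) == 0L) next
    i <- ov$a_index
    j <- ov$b_index
    peak_id <- ifelse(is.na(peaks$name[j]) | !nzchar(peaks$name[j]),
                      paste0("peak", j), peaks$name[j])
    out[[tf]] <- data.frame(
      gene = tx$gene[i],
      tf = tf,
      contig = ov$contig,
      start = if (clip_to_window) ov$start else peaks$start[j],
      end = if (clip_to_window) ov$end else peaks$end[j],
      tx_strand = tx$strand[i],
      source_transcript = tx$accession[i],
      source_peak = peak_id,
      stringsAsFactors = FALSE
    )
  }
  regions <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(gene = character(0), tf = character(0), contig = character(0),
               start = numeric(0), end = numeric(0), tx_strand = character(0),
               source_transcript = character(0), source_peak = character(0),
               stringsAsFactors = FALSE)
  key <- paste(regions$gene, regions$tf, regions$contig, regions$start,
               regions$end, sep = "\r")
  regions <- regions[!duplicated(key), , drop = FALSE]
  regions <- regions[order(regions$gene, regions$tf, regions$contig,
                           regions$start, regions$end), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Annotate motif hits with regulatory-element segmentation labels
#'
#' Sets each hit's `regulatory_elements` field to the lexicographically
#' sorted unique labels of all segmentation intervals overlapping the hit's
#' genomic span by at least 1 bp, or `"."` when none overlap. Hit order is
#' preserved.
#'
#' @param hits Motif-hit table with `contig`, `start`, `end` columns (see
#'   [run_scan()]).
#' @param segmentation Interval table whose `label` column carries the
#'   regulatory-element class (e.g. `PLS`, `dELS`).
#' @return `hits` with its `regulatory_elements` column (re)computed.
#' @export
annotate_with_segmentation <- function(hits, segmentation) {
  hits$regulatory_elements <- rep(".", nrow(hits))
  if (nrow(hits) == 0L || is.null(segmentation) || nrow(segmentation) == 0L)
    return(hits)
  validate_intervals(segmentation)
  hi <- genomic_intervals(hits$contig, hits$start, hits$end)
  ov <- intersect_intervals(hi, segmentation)
  if (nrow(ov) == 0L) return(hits)
  lab <- split(segmentation$label[ov$b_index], ov$a_index)
  for (k in names(lab)) {
    labs <- sort_labels(unique(lab[[k]]))
    labs <- labs[!is.na(labs) & nzchar(labs)]
    if (length(labs) > 0L)
      hits$regulatory_elements[as.integer(k)] <- paste(labs, collapse = ",")
  }
  hits
}
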