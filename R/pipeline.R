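#' Configuration for an ARE scan
#'
#' Bundles and validates all tunable parameters of the scanning pipeline.
#' Defaults mirror the analysis the package implements: a 5000 bp upstream
#' extension of each transcript, retention of sites with relative score of
#' at least 0.8, both-strand scanning, pseudocount 1 with a uniform
#' background, and the NRF2/small-MAF/BACH1 transcription-factor panel.
#'
#' @param gene_list Non-empty character vector of gene symbols and/or
#'   transcript accessions to analyse.
#' @param upstream_bp Upstream extension in bp (default 5000).
#' @param threshold Relative-score cutoff in `[0, 1]` (default 0.8).
#' @param strands `"both"` (default) or `"plus_only"`.
#' @param pseudocount PFM pseudocount (default 1).
#' @param background Background base probabilities, A/C/G/T (default
#'   uniform).
#' @param tf_labels Transcription factors whose peak sets are used (default
#'   `NFE2L2`, `MAFF`, `MAFK`, `MAFG`, `BACH1`). `NULL` keeps every peak
#'   set supplied.
#' @param clip_to_window Scan the peak-window overlap (default `TRUE`)
#'   rather than whole peaks.
#' @param score_style Report score rendering, `"fraction"` or `"percent"`.
#' @param min_overlap Minimum peak-window overlap in bp (default 1).
#' @param genomic_orientation Report each motif as matched on its genomic
#'   strand instead of re-oriented to transcript sense (default `FALSE`).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(gene_list,
                        upstream_bp = 5000L,
                        threshold = 0.8,
                        strands = c("both", "plus_only"),
                        pseudocount = 1,
                        background = rep(0.25, 4),
                        tf_labels = c("NFE2L2", "MAFF", "MAFK", "MAFG",
                                      "BACH1"),
                        clip_to_window = TRUE,
                        score_style = c("fraction", "percent"),
                        min_overlap = 1L,
                        genomic_orientation = FALSE) {
  strands <- match.arg(strands)
  score_style <- match.arg(score_style)
  if (missing(gene_list) || length(gene_list) == 0L)
    stop("configuration error: gene_list must be non-empty")
  if (threshold < 0 || threshold > 1)
    stop("configuration error: threshold must be within [0, 1]")
  if (upstream_bp < 0)
    stop("configuration error: upstream_bp must be non-negative")
  structure(list(gene_list = as.character(gene_list),
                 upstream_bp = as.numeric(upstream_bp),
                 threshold = threshold, strands = strands,
                 pseudocount = pseudocount, background = background,
                 tf_labels = tf_labels, clip_to_window = clip_to_window,
                 score_style = score_style, min_overlap = min_overlap,
                 genomic_orientation = genomic_orientation),
            class = "scan_config")
}

#' Map a window offset within a search region back to the genome
#'
#' Scanning is always performed on the `+` strand sequence of a region, so
#' the mapping is strand-independent: genomic start = region start +
#' offset.
#'
#' @param region One-row search-region table (see
#'   [build_search_regions()]), or any one-row table with `contig`,
#'   `start`, `end`.
#' @param offset 0-based window offset within the region.
#' @param width Window (matrix) width in bp.
#' @return A one-row interval table for the window's genomic span.
#' @export
map_offset_to_genome <- function(region, offset, width) {
  stopifnot(nrow(region) == 1L)
  if (offset < 0 || offset > (region$end - region$start - width))
    stop("internal consistency error: window offset ", offset,
         " outside region of length ", region$end - region$start)
  genomic_intervals(region$contig, region$start + offset,
                    region$start + offset + width)
}

#' Strand of a hit relative to its transcript
#'
#' `"+"` (sense) when the hit's genomic strand equals the transcript
#' strand, `"-"` (antisense) otherwise.
#'
#' @param genomic_strand,transcript_strand Vectors over `{"+", "-"}`.
#' @return Character vector over `{"+", "-"}`.
#' @export
resolve_relative_strand <- function(genomic_strand, transcript_strand) {
  stopifnot(all(genomic_strand %in% c("+", "-")),
            all(transcript_strand %in% c("+", "-")))
  ifelse(genomic_strand == transcript_strand, "+", "-")
}

#' Run the ARE scanning pipeline
#'
#' End-to-end analysis: restrict transcripts to the configured gene list,
#' extend each transcript upstream of its TSS, intersect the windows with
#' each transcription factor's ChIP-seq peaks, extract the overlap
#' sequences from the genome, scan them on both strands with the log2-odds
#' PSSM derived from `pfm`, retain windows whose relative score reaches the
#' threshold, map them back to genomic coordinates, merge identical sites
#' found under several TFs' peaks, and annotate the survivors with
#' regulatory-element segmentation labels.
#'
#' @param config A [scan_config()].
#' @param genome Genome object ([read_fasta()]).
#' @param tx Transcript table ([transcripts()]).
#' @param peaks_by_tf Named list: TF label to peak interval table.
#' @param pfm `jaspar_pfm` object or 4 x width count matrix.
#' @param segmentation Optional labelled interval table (cCRE segmentation).
#' @param verbose Log per-stage counts to stderr (default `FALSE`).
#' @return An object of class `are_scan`: a list with `hits` (one row per
#'   retained site: `gene`, `contig`, `start`, `end`, `motif`, `absolute`,
#'   `relative`, `genomic_strand`, `relative_strand`, `tfs`,
#'   `regulatory_elements`), `regions`, `config`, `pssm` and `log`
#'   (per-stage counts).
#' @examples
#' ds <- generate_dataset(synth_params(seed = 42))
#' cfg <- scan_config(gene_list = unique(ds$transcripts$gene))
#' scan <- run_scan(cfg, ds$genome, ds$transcripts, ds$peaks_by_tf,
#'                  ds$pfm, ds$segmentation)
#' summary(scan)
#' @export
run_scan <- function(config, genome, tx, peaks_by_tf, pfm,
                     segmentation = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scan_config"))
  t0 <- proc.time()[["elapsed"]]
  say <- function(stage, count) {
    if (verbose)
      message(sprintf("[%s] %s: %s (%.2fs)", "arescan", stage,
                      paste(count, collapse = ", "),
                      proc.time()[["elapsed"]] - t0))
  }

  keep <- tx$gene %in% config$gene_list | tx$accession %in% config$gene_list
  tx <- tx[keep, , drop = FALSE]
  if (nrow(tx) == 0L)
    stop("configuration error: no transcripts match gene_list")
  say("transcripts", nrow(tx))

  if (!is.null(config$tf_labels))
    peaks_by_tf <- peaks_by_tf[intersect(names(peaks_by_tf),
                                         config$tf_labels)]

  pssm <- pfm_to_pssm(pfm, pseudocount = config$pseudocount,
                      background = config$background)
  W <- pssm$width

  contig_lengths <- nchar(genome)
  names(contig_lengths) <- names(genome)
  regions <- build_search_regions(tx, peaks_by_tf,
                                  upstream_bp = config$upstream_bp,
                                  contig_lengths = contig_lengths,
                                  clip_to_window = config$clip_to_window,
                                  min_overlap = config$min_overlap)
  say("search regions", nrow(regions))

  bp_scanned <- 0
  windows_scored <- 0L
  hit_rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, , drop = FALSE]
    seq_str <- extract_sequence(genome, reg, "+")
    bp_scanned <- bp_scanned + nchar(seq_str)
    ws <- scan_sequence(pssm, seq_str, threshold = config$threshold,
                        strands = config$strands)
    n_off <- max(0L, nchar(seq_str) - W + 1L)
    windows_scored <- windows_scored +
      n_off * (if (config$strands == "both") 2L else 1L) -
      attr(ws, "n_not_scorable")
    if (nrow(ws) == 0L) next
    rel_strand <- resolve_relative_strand(ws$strand, reg$tx_strand)
    motif <- ws$matched
    if (!config$genomic_orientation) {
      flip <- rel_strand == "-"
      if (any(flip)) motif[flip] <- reverse_complement(motif[flip])
    }
    hit_rows[[i]] <- data.frame(
      gene = reg$gene,
      contig = reg$contig,
      start = reg$start + ws$offset,
      end = reg$start + ws$offset + W,
      motif = motif,
      absolute = ws$absolute,
      relative = ws$relative,
      genomic_strand = ws$strand,
      relative_strand = rel_strand,
      tfs = reg$tf,
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, c(hit_rows, list(empty_hits())))
  say("bp scanned / windows scored", c(bp_scanned, windows_scored))
  n_retained <- nrow(hits)
  say("hits retained", n_retained)

  # merge identical sites (same gene, span, genomic strand, motif) found
  # under several TFs' peaks
  if (nrow(hits) > 0L) {
    key <- paste(hits$gene, hits$contig, hits$start, hits$end,
                 hits$genomic_strand, hits$motif, sep = "\r")
    tf_merged <- vapply(split(hits$tfs, key),
                        function(x) paste(sort_labels(unique(x)),
                                          collapse = ","), "")
    hits <- hits[!duplicated(key), , drop = FALSE]
    hits$tfs <- tf_merged[paste(hits$gene, hits$contig, hits$start,
                                hits$end, hits$genomic_strand, hits$motif,
                                sep = "\r")]
  }
  say("hits after dedupe", nrow(hits))

  hits <- annotate_with_segmentation(hits, segmentation)
  hits <- hits[order(hits$gene, hits$contig, hits$start,
                     match(hits$genomic_strand, c("+", "-"))), ,
               drop = FALSE]
  rownames(hits) <- NULL

  structure(list(
    hits = hits,
    regions = regions,
    config = config,
    pssm = pssm,
    log = list(transcripts = nrow(tx), regions = nrow(regions),
               bp_scanned = bp_scanned, windows_scored = windows_scored,
               hits_retained = n_retained, hits_after_dedupe = nrow(hits))
  ), class = "are_scan")
}

empty_hits <- function() {
  data.frame(gene = character(0), contig = character(0), start = numeric(0),
             end = numeric(0), motif = character(0), absolute = numeric(0),
             relative = numeric(0), genomic_strand = character(0),
             relative_strand = character(0), tfs = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.are_scan <- function(x, ...) {
  cat("ARE scan:", x$log$hits_after_dedupe, "site(s) retained at relative",
      "score >=", x$config$threshold, "\n")
  cat("  ", x$log$transcripts, "transcript(s),", x$log$regions,
      "search region(s),", format_bp(x$log$bp_scanned), "bp scanned\n")
  if (nrow(x$hits) > 0L)
    print(utils::head(x$hits[, c("gene", "contig", "start", "end", "motif",
                                 "relative", "relative_strand", "tfs")],
                      10L))
  invisible(x)
}

#' @export
summary.are_scan <- function(object, ...) {
  cat("ARE scanning pipeline summary\n")
  cat(sprintf("  threshold %.2f, upstream %s bp, strands: %s\n",
              object$config$threshold, format_bp(object$config$upstream_bp),
              object$config$strands))
  for (nm in names(object$log))
    cat(sprintf("  %-18s %s\n", nm, format_bp(object$log[[nm]])))
  if (nrow(object$hits) > 0L) {
    cat("  sites per gene:\n")
    print(table(object$hits$gene))
  }
  invisible(object)
}

#' @export
as.data.frame.are_scan <- function(x, ...) x$hits
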