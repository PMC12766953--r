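#' Parameters for synthetic dataset generation
#'
#' Describes a miniature study: a small multi-contig genome, one stranded
#' transcript per gene, per-TF ChIP-seq peaks placed to overlap promoter
#' windows with a given probability, a PLS/dELS segmentation, and planted
#' motif instances (high-scoring consensus copies and below-threshold
#' decoys) whose expected scores are computed by a direct oracle.
#'
#' @param contig_lengths Named numeric vector of contig lengths (default
#'   two 50,000 bp contigs).
#' @param gc Target GC fraction of the background sequence (default 0.5).
#' @param genes Gene symbols, one transcript each (default the seven
#'   inflammasome/pyroptosis genes `Nlrp3`, `Asc`, `Casp1`, `Gsdmd`,
#'   `Il1b`, `Il18rap`, `Aim2` — naming only, no biological sequence
#'   content is emulated).
#' @param tfs Transcription-factor labels receiving peak sets (default
#'   `NFE2L2`, `MAFF`, `MAFK`, `MAFG`, `BACH1`).
#' @param peaks_per_tf Peaks generated per TF (default 3).
#' @param p_peak_in_window Probability a peak is placed inside a promoter
#'   window rather than at a random background position (default 0.7).
#' @param n_consensus Planted per-position-argmax (consensus) instances
#'   (default 5).
#' @param n_decoys Planted mutated instances scoring below threshold
#'   (default 5).
#' @param tx_length Transcript body length in bp (default 2000).
#' @param upstream_bp Upstream window extension in bp (default 5000).
#' @param seed Integer seed driving every random choice (default 42).
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(contig_lengths = c(chrS1 = 50000, chrS2 = 50000),
                         gc = 0.5,
                         genes = c("Nlrp3", "Asc", "Casp1", "Gsdmd",
                                   "Il1b", "Il18rap", "Aim2"),
                         tfs = c("NFE2L2", "MAFF", "MAFK", "MAFG", "BACH1"),
                         peaks_per_tf = 3L,
                         p_peak_in_window = 0.7,
                         n_consensus = 5L,
                         n_decoys = 5L,
                         tx_length = 2000L,
                         upstream_bp = 5000L,
                         seed = 42L) {
  if (gc < 0 || gc > 1) stop("gc must be within [0, 1]")
  stopifnot(peaks_per_tf >= 0, n_consensus >= 0, n_decoys >= 0,
            all(contig_lengths > 0), length(genes) > 0)
  structure(as.list(environment()), class = "synth_params")
}

#' Sample a random nucleotide sequence
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2` from the current RNG stream, so results are
#' deterministic under `set.seed()`.
#'
#' @param length Sequence length (>= 0).
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @return A nucleotide string.
#' @export
sample_sequence <- function(length, gc = 0.5) {
  if (gc < 0 || gc > 1) stop("gc must be within [0, 1]")
  stopifnot(length >= 0)
  if (length == 0L) return("")
  paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Plant a motif instance into a sequence
#'
#' Replaces the bases at `[position, position + nchar(motif))` (0-based)
#' with `motif` (strand `+`) or its reverse complement (strand `-`),
#' leaving the rest of the sequence unchanged. Overlap management between
#' successive plants is the caller's job; [generate_dataset()] keeps a
#' ledger of occupied spans and resamples positions on collision.
#'
#' @param sequence Host nucleotide string.
#' @param position 0-based start of the replacement.
#' @param motif Motif string (as it matches the scoring matrix).
#' @param genomic_strand `"+"` or `"-"`.
#' @return The modified sequence.
#' @examples
#' plant_motif_instance("CCCCCCCC", 3, "AG", "+")  # "CCCAGCCC"
#' plant_motif_instance("CCCCCCCC", 3, "AG", "-")  # "CCCCTCCC"
#' @export
plant_motif_instance <- function(sequence, position, motif, genomic_strand) {
  stopifnot(genomic_strand %in% c("+", "-"))
  w <- nchar(motif)
  if (position < 0 || position + w > nchar(sequence))
    stop("plant out of bounds: position ", position, " + width ", w,
         " exceeds sequence length ", nchar(sequence))
  ins <- if (genomic_strand == "-") reverse_complement(motif) else motif
  paste0(substr(sequence, 1L, position), ins,
         substr(sequence, position + w + 1L, nchar(sequence)))
}

#' Built-in demonstration motif
#'
#' An 11-position synthetic count matrix whose per-position argmax spells
#' `TTGACTCAGCA`, resembling an ARE-like consensus. This is a demonstration
#' matrix for the synthetic pipeline, not a JASPAR profile.
#'
#' @return A `jaspar_pfm` object.
#' @export
demo_pfm <- function() {
  consensus <- strsplit("TTGACTCAGCA", "")[[1L]]
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = 4L, ncol = length(consensus),
                   dimnames = list(bases, NULL))
  minor <- c(2, 0, 1)  # fixed low counts cycled over the non-consensus rows
  for (p in seq_along(consensus)) {
    counts[, p] <- minor[(seq_len(4L) + p) %% 3L + 1L]
    counts[consensus[p], p] <- 12
  }
  structure(list(motif_id = "SYNTH0001", motif_name = "ARE_demo_synthetic",
                 width = length(consensus), counts = counts),
            class = "jaspar_pfm")
}

# Direct oracle for the relative score of one window, evaluated straight
# from the PFM counts (kept independent of pfm_to_pssm/score_window so it
# can verify them).
oracle_relative <- function(counts, window, pseudocount = 1,
                            background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(window, "")[[1L]]
  abs_score <- 0
  min_score <- 0
  max_score <- 0
  for (p in seq_along(chars)) {
    col <- counts[, p] + pseudocount
    probs <- col / sum(col)
    cell <- log2(probs / background)
    abs_score <- abs_score + cell[match(chars[p], bases)]
    min_score <- min_score + min(cell)
    max_score <- max_score + max(cell)
  }
  unname((abs_score - min_score) / (max_score - min_score))
}

pfm_consensus <- function(pfm) {
  bases <- c("A", "C", "G", "T")
  paste(bases[apply(pfm$counts, 2L, which.max)], collapse = "")
}

#' Generate a synthetic scanning dataset with planted truth
#'
#' Builds every input the scanning pipeline consumes — genome, stranded
#' transcripts, per-TF peaks, PLS/dELS segmentation — and plants motif
#' instances at known positions strictly inside peak-window overlap
#' regions: `n_consensus` copies of the matrix consensus (oracle relative
#' score 1, expected to be detected) and `n_decoys` mutated copies whose
#' oracle relative score is below `threshold` in both orientations
#' (expected not to be detected). The truth ledger records each instance
#' with its oracle-computed score; oracle scores are evaluated directly
#' from the PFM counts, never by the scanner.
#'
#' @param params A [synth_params()] object.
#' @param pfm Motif count matrix to plant and scan with (default
#'   [demo_pfm()]).
#' @param threshold Relative-score cutoff the truth is evaluated against
#'   (default 0.8).
#' @return A list of class `are_synth_dataset` with elements `genome`,
#'   `transcripts`, `peaks_by_tf`, `segmentation`, `pfm`, and `truth` (a
#'   `synthetic_truth` list: `instances` data.frame, `seed`, `params`).
#' @examples
#' ds <- generate_dataset(synth_params(seed = 7))
#' ds$truth$instances[, c("contig", "start", "strand", "expected_detected")]
#' @export
generate_dataset <- function(params = synth_params(), pfm = demo_pfm(),
                             threshold = 0.8) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  W <- pfm$width

  genome <- vapply(params$contig_lengths,
                   function(len) sample_sequence(len, params$gc), "")
  names(genome) <- names(params$contig_lengths)
  class(genome) <- "genome_sequence"

  # one transcript per gene, laid out in non-overlapping window slots so
  # promoter windows never collide
  slot <- params$upstream_bp + params$tx_length + 300
  contigs <- names(genome)
  n_slots <- floor(params$contig_lengths / slot)
  if (sum(n_slots) < length(params$genes))
    stop("generation error: contigs too short for ", length(params$genes),
         " transcript windows; use larger contigs")
  assignment <- rep(contigs, times = n_slots)[seq_along(params$genes)]
  tx_rows <- vector("list", length(params$genes))
  slot_used <- stats::setNames(rep(0L, length(contigs)), contigs)
  for (g in seq_along(params$genes)) {
    ctg <- assignment[g]
    off <- slot_used[[ctg]] * slot + sample(0:200, 1L) + 50
    slot_used[[ctg]] <- slot_used[[ctg]] + 1L
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") {
      s <- off + params$upstream_bp
      e <- s + params$tx_length
    } else {
      s <- off
      e <- s + params$tx_length
    }
    tx_rows[[g]] <- transcripts(params$genes[g], ctg, s, e, strand,
                                gene = params$genes[g])
  }
  tx <- do.call(rbind, tx_rows)

  contig_lengths <- params$contig_lengths
  windows <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i)
    extend_upstream(tx[i, , drop = FALSE], params$upstream_bp,
                    contig_length = contig_lengths[[tx$contig[i]]])))

  peaks_by_tf <- list()
  for (tf in params$tfs) {
    rows <- vector("list", params$peaks_per_tf)
    for (k in seq_len(params$peaks_per_tf)) {
      w <- sample(200:400, 1L)
      if (stats::runif(1L) < params$p_peak_in_window) {
        i <- sample(nrow(windows), 1L)
        lo <- windows$start[i]
        hi <- max(lo, windows$end[i] - w)
        s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        ctg <- windows$contig[i]
      } else {
        ctg <- sample(contigs, 1L)
        s <- sample.int(contig_lengths[[ctg]] - w + 1L, 1L) - 1L
      }
      rows[[k]] <- genomic_intervals(ctg, s, s + w,
                                     name = paste0(tf, "_", k))
    }
    peaks_by_tf[[tf]] <- do.call(rbind, rows)
  }

  regions <- build_search_regions(tx, peaks_by_tf,
                                  upstream_bp = params$upstream_bp,
                                  contig_lengths = contig_lengths)
  wide <- regions[regions$end - regions$start >= W, , drop = FALSE]
  if (nrow(wide) == 0L && params$n_consensus + params$n_decoys > 0L)
    stop("generation error: no peak-window region wide enough to plant ",
         "instances; use larger contigs or more peaks")

  occupied <- list()  # per contig: 2-col matrix of planted spans
  overlaps_plant <- function(ctg, s, e) {
    occ <- occupied[[ctg]]
    !is.null(occ) && any(s < occ[, 2L] & occ[, 1L] < e)
  }
  place <- function(motif_seq) {
    for (attempt in seq_len(100L)) {
      r <- wide[sample(nrow(wide), 1L), , drop = FALSE]
      off <- sample.int(r$end - r$start - W + 1L, 1L) - 1L
      s <- r$start + off
      if (overlaps_plant(r$contig, s, s + W)) next
      strand <- sample(c("+", "-"), 1L)
      genome[[r$contig]] <<- plant_motif_instance(genome[[r$contig]], s,
                                                  motif_seq, strand)
      occupied[[r$contig]] <<- rbind(occupied[[r$contig]], c(s, s + W))
      return(list(contig = r$contig, start = s, end = s + W,
                  strand = strand, gene = r$gene, tf = r$tf))
    }
    stop("generation error: could not place instance without overlap ",
         "after 100 attempts; use larger contigs")
  }

  consensus <- pfm_consensus(pfm)
  bases <- c("A", "C", "G", "T")
  make_decoy <- function() {
    s <- consensus
    for (attempt in seq_len(W * 4L)) {
      p <- sample(W, 1L)
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, cur), 1L)
      if (oracle_relative(pfm$counts, s) < threshold &&
          oracle_relative(pfm$counts, reverse_complement(s)) < threshold)
        return(s)
    }
    stop("generation error: decoy mutation did not fall below threshold")
  }

  inst <- vector("list", params$n_consensus + params$n_decoys)
  for (i in seq_len(params$n_consensus)) {
    loc <- place(consensus)
    inst[[i]] <- data.frame(loc, sequence = consensus,
                            oracle_relative = oracle_relative(pfm$counts,
                                                              consensus),
                            stringsAsFactors = FALSE)
  }
  for (i in seq_len(params$n_decoys)) {
    d <- make_decoy()
    loc <- place(d)
    inst[[params$n_consensus + i]] <-
      data.frame(loc, sequence = d,
                 oracle_relative = oracle_relative(pfm$counts, d),
                 stringsAsFactors = FALSE)
  }
  instances <- if (length(inst) > 0L) do.call(rbind, inst) else
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), gene = character(0), tf = character(0),
               sequence = character(0), oracle_relative = numeric(0),
               stringsAsFactors = FALSE)
  instances$expected_detected <- instances$oracle_relative >= threshold

  # segmentation: PLS over the 500 bp promoter-proximal to each TSS, dELS
  # over the cores of peaks distal to every TSS
  tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  seg_rows <- lapply(seq_len(nrow(tx)), function(i) {
    if (tx$strand[i] == "+") {
      s <- max(0, tss[i] - 500)
      e <- tss[i]
    } else {
      s <- tss[i]
      e <- min(contig_lengths[[tx$contig[i]]], tss[i] + 500)
    }
    genomic_intervals(tx$contig[i], s, e, name = "PLS", label = "PLS")
  })
  all_peaks <- do.call(rbind, peaks_by_tf)
  if (!is.null(all_peaks) && nrow(all_peaks) > 0L) {
    ctr <- floor((all_peaks$start + all_peaks$end) / 2)
    for (k in seq_len(nrow(all_peaks))) {
      same <- tx$contig == all_peaks$contig[k]
      dist <- if (any(same)) min(abs(tss[same] - ctr[k])) else Inf
      if (dist > 1500) {
        s <- max(0, ctr[k] - 100)
        e <- min(contig_lengths[[all_peaks$contig[k]]], ctr[k] + 100)
        seg_rows[[length(seg_rows) + 1L]] <-
          genomic_intervals(all_peaks$contig[k], s, e,
                            name = "dELS", label = "dELS")
      }
    }
  }
  segmentation <- do.call(rbind, seg_rows)
  segmentation <- segmentation[order(segmentation$contig,
                                     segmentation$start), , drop = FALSE]
  rownames(segmentation) <- NULL

  truth <- structure(list(instances = instances, seed = params$seed,
                          params = params), class = "synthetic_truth")
  structure(list(genome = genome, transcripts = tx,
                 peaks_by_tf = peaks_by_tf, segmentation = segmentation,
                 pfm = pfm, truth = truth),
            class = "are_synth_dataset")
}

#' Evaluate hit recovery against the planted truth
#'
#' Matches reported hits to planted instances by exact genomic span and
#' strand.
#'
#' @param hits Motif-hit table or `are_scan` object from [run_scan()].
#' @param truth `synthetic_truth` object from the same dataset.
#' @return A list: `recall` (fraction of expected-detected instances
#'   recovered), `decoys_reported` (planted below-threshold instances that
#'   appear among the hits; 0 for a correct scanner), `unplanted_hits`
#'   (distinct reported sites matching no planted instance — chance
#'   background matches, reported for information).
#' @export
evaluate_recovery <- function(hits, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (inherits(hits, "are_scan")) hits <- hits$hits
  hit_keys <- unique(paste(hits$contig, hits$start, hits$end,
                           hits$genomic_strand))
  ins <- truth$instances
  truth_keys <- paste(ins$contig, ins$start, ins$end, ins$strand)
  expected <- truth_keys[ins$expected_detected]
  decoys <- truth_keys[!ins$expected_detected]
  list(
    recall = if (length(expected) == 0L) NA_real_
             else mean(expected %in% hit_keys),
    decoys_reported = sum(decoys %in% hit_keys),
    unplanted_hits = sum(!hit_keys %in% truth_keys)
  )
}

#' Serialize a synthetic dataset to plain-text files
#'
#' Writes `genome.fa`, `transcripts.bed` (BED 6, name = accession),
#' `peaks_<TF>.bed`, `segmentation.bed` (label in column 4) and
#' `truth.tsv` into a directory, in the formats the pipeline's readers
#' consume.
#'
#' @param ds An `are_synth_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "are_synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$genome, file.path(dir, "genome.fa"))
  tx <- ds$transcripts
  write_bed(genomic_intervals(tx$contig, tx$start, tx$end,
                              name = tx$accession, strand = tx$strand),
            file.path(dir, "transcripts.bed"))
  for (tf in names(ds$peaks_by_tf))
    write_bed(ds$peaks_by_tf[[tf]],
              file.path(dir, paste0("peaks_", tf, ".bed")))
  write_bed(ds$segmentation, file.path(dir, "segmentation.bed"))
  utils::write.table(ds$truth$instances, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a serialized synthetic dataset back
#'
#' Inverse of [write_dataset()] (the generation parameters and PFM are not
#' serialized and come back as `NULL`).
#'
#' @param dir Directory written by [write_dataset()].
#' @return A list with `genome`, `transcripts`, `peaks_by_tf`,
#'   `segmentation`, and `truth_instances`.
#' @export
read_dataset <- function(dir) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  tx_bed <- read_bed(file.path(dir, "transcripts.bed"), min_columns = 6L)
  peak_files <- list.files(dir, pattern = "^peaks_.*\\.bed$",
                           full.names = TRUE)
  peaks_by_tf <- lapply(peak_files, read_bed)
  names(peaks_by_tf) <- sub("^peaks_(.*)\\.bed$", "\\1",
                            basename(peak_files))
  truth_path <- file.path(dir, "truth.tsv")
  list(
    genome = genome,
    transcripts = transcripts_from_bed(tx_bed),
    peaks_by_tf = peaks_by_tf,
    segmentation = read_bed(file.path(dir, "segmentation.bed"),
                            min_columns = 4L, label_column = 4L),
    truth_instances = if (file.exists(truth_path))
      utils::read.delim(truth_path, stringsAsFactors = FALSE) else NULL
  )
}
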