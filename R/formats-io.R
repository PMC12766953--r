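#' Read a genome from a FASTA file
#'
#' Parses FASTA text into a genome object: a named character vector of
#' uppercase nucleotide strings over `{A,C,G,T,N}`. Contig names are the
#' header token up to the first whitespace. Residues outside `{A,C,G,T,N}`
#' after uppercasing (ambiguity codes, soft-masking leftovers) are coerced
#' to `N`; the number of coerced residues is recorded in the `parse_log`
#' attribute rather than rejected, so real genomes pass through.
#'
#' @param source Path to a FASTA file, or a connection.
#' @return A named character vector of class `genome_sequence`, one element
#'   per contig, with attribute `parse_log` (a list with `n_contigs` and
#'   `n_coerced_to_N`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(source) {
  path <- source
  if (inherits(source, "connection")) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(readLines(source), path)
  }
  info <- file.size(path)
  if (is.na(info) || info == 0L) stop("FASTA format error: empty input")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("FASTA format error: ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no records")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  n_bad <- sum(nchar(seqs) - nchar(gsub("[^ACGTN]", "", seqs)))
  if (n_bad > 0L) seqs <- gsub("[^ACGTN]", "N", seqs)
  structure(seqs, class = "genome_sequence",
            parse_log = list(n_contigs = length(seqs),
                             n_coerced_to_N = n_bad))
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output file path.
#' @param line_width Sequence wrapping width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, line_width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Parses BED 3-6 text into an interval table (0-based half-open, exactly as
#' written — no coordinate shifting). Lines starting with `track`, `browser`
#' or `#` are skipped and counted in the `parse_log` attribute. Column 4 (if
#' present) becomes `name`, column 6 becomes `strand` (`"."` when absent).
#' For segmentation files whose class label lives in column 4, set
#' `label_column = 4` to copy it into `label` as well.
#'
#' @param source Path to a BED file, or a connection.
#' @param min_columns Minimum number of columns each record must have
#'   (default 3); records with fewer raise an error naming the line.
#' @param label_column Optional column index whose value is copied into the
#'   `label` field (e.g. 4 for cCRE segmentation BED files).
#' @return An interval table (see [genomic_intervals()]) in input order,
#'   with attribute `parse_log` (list with `n_records`, `n_skipped`).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpeak1\t0\t+", bed)
#' read_bed(bed)
#' @export
read_bed <- function(source, min_columns = 3L, label_column = NA) {
  lines <- readLines(source)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  n_skipped <- sum(!keep)
  lines_kept <- lines[keep]
  lineno <- which(keep)
  if (length(lines_kept) == 0L) {
    out <- empty_intervals()
    attr(out, "parse_log") <- list(n_records = 0L, n_skipped = n_skipped)
    return(out)
  }
  fields <- strsplit(lines_kept, "\t", fixed = TRUE)
  ncol_rec <- lengths(fields)
  if (any(ncol_rec < min_columns))
    stop("BED record error at line ", lineno[which(ncol_rec < min_columns)[1L]],
         ": fewer than ", min_columns, " columns")
  get_col <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  contig <- get_col(1L)
  start <- suppressWarnings(as.numeric(get_col(2L)))
  end <- suppressWarnings(as.numeric(get_col(3L)))
  bad <- is.na(start) | is.na(end) | start != trunc(start) | end != trunc(end)
  if (any(bad))
    stop("BED record error at line ", lineno[which(bad)[1L]],
         ": non-integer coordinate")
  if (any(start >= end))
    stop("BED record error at line ", lineno[which(start >= end)[1L]],
         ": empty or inverted interval (start >= end)")
  strand <- get_col(6L)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  label <- if (!is.na(label_column)) get_col(as.integer(label_column))
           else NA_character_
  out <- genomic_intervals(contig, start, end, name = get_col(4L),
                           strand = strand, label = label)
  attr(out, "parse_log") <- list(n_records = nrow(out), n_skipped = n_skipped)
  out
}

#' Write genomic intervals to a BED file
#'
#' Writes BED 6 when any interval carries a name or strand, BED 3 otherwise.
#' Missing names are written as `"."`; the score column is 0.
#'
#' @param gi Interval table (see [genomic_intervals()]).
#' @param path Output file path or connection.
#' @return Number of records written, invisibly.
#' @export
write_bed <- function(gi, path) {
  validate_intervals(gi)
  has_meta <- any(!is.na(gi$name)) || any(gi$strand != ".")
  lines <- if (nrow(gi) == 0L) character(0)
  else if (has_meta)
    paste(gi$contig, format_bp(gi$start), format_bp(gi$end),
          ifelse(is.na(gi$name), ".", gi$name), 0L, gi$strand, sep = "\t")
  else paste(gi$contig, format_bp(gi$start), format_bp(gi$end), sep = "\t")
  writeLines(lines, path)
  invisible(nrow(gi))
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a JASPAR position frequency matrix
#'
#' Parses JASPAR PFM text: a `>ID name` header followed by four count rows
#' in alphabet order A, C, G, T. Both common dialects are accepted — the
#' bracketed form (`A [ 3 0 ]`) and the bare whitespace form (`3 0`);
#' when base letters are present they are honoured, otherwise rows are
#' assigned in A, C, G, T order. Counts may be non-integer.
#'
#' @param source Path to a JASPAR PFM text file, or a connection.
#' @return A list of class `jaspar_pfm` with fields `motif_id`,
#'   `motif_name`, `width`, and `counts` (a 4 x width numeric matrix with
#'   rownames `A`, `C`, `G`, `T`).
#' @examples
#' pfm_txt <- textConnection(c(">MA0000.1 TEST",
#'                             "A [ 3 0 ]", "C [ 1 0 ]",
#'                             "G [ 0 3 ]", "T [ 0 1 ]"))
#' read_jaspar_pfm(pfm_txt)
#' @export
read_jaspar_pfm <- function(source) {
  lines <- readLines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[1L], ">"))
    stop("JASPAR format error: missing '>' header line")
  header <- trimws(sub("^>", "", lines[1L]))
  toks <- strsplit(header, "\\s+")[[1L]]
  motif_id <- toks[1L]
  motif_name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ")
                else motif_id
  rows <- lines[-1L]
  if (length(rows) != 4L)
    stop("JASPAR format error: expected 4 count rows, found ", length(rows))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(numeric(0), nrow = 4L, dimnames = list(bases, NULL))
  parsed <- vector("list", 4L)
  row_base <- character(4L)
  for (i in seq_len(4L)) {
    r <- chartr("[]", "  ", rows[i])
    tk <- strsplit(trimws(r), "\\s+")[[1L]]
    if (length(tk) > 0L && tk[1L] %in% bases) {
      row_base[i] <- tk[1L]
      tk <- tk[-1L]
    } else row_base[i] <- bases[i]
    vals <- suppressWarnings(as.numeric(tk))
    if (length(vals) == 0L || anyNA(vals))
      stop("JASPAR format error: unparseable count row: ", rows[i])
    if (any(vals < 0)) stop("JASPAR format error: negative count")
    parsed[[i]] <- vals
  }
  if (length(unique(lengths(parsed))) != 1L)
    stop("JASPAR format error: count rows of unequal length")
  if (!setequal(row_base, bases))
    stop("JASPAR format error: base rows must cover A, C, G, T")
  width <- length(parsed[[1L]])
  counts <- matrix(0, nrow = 4L, ncol = width, dimnames = list(bases, NULL))
  for (i in seq_len(4L)) counts[row_base[i], ] <- parsed[[i]]
  if (any(colSums(counts) == 0))
    stop("JASPAR format error: column with all-zero counts")
  structure(list(motif_id = motif_id, motif_name = motif_name,
                 width = width, counts = counts),
            class = "jaspar_pfm")
}

#' @export
print.jaspar_pfm <- function(x, ...) {
  cat("JASPAR PFM", x$motif_id, paste0("(", x$motif_name, ")"),
      "- width", x$width, "\n")
  print(x$counts)
  invisible(x)
}

#' Extract a genomic sequence slice
#'
#' Returns the half-open slice `[start, end)` of the named contig; for
#' `strand = "-"` the reverse complement of that slice, so the result reads
#' 5' to 3' along the requested strand.
#'
#' @param genome Genome object from [read_fasta()] (or any named character
#'   vector of uppercase sequences).
#' @param interval A one-row interval table (see [genomic_intervals()]).
#' @param strand `"+"` (default) or `"-"`.
#' @return A nucleotide string of length `end - start`.
#' @examples
#' g <- structure(c(c1 = "ACGTACGT"), class = "genome_sequence")
#' extract_sequence(g, genomic_intervals("c1", 1, 5))        # "CGTA"
#' extract_sequence(g, genomic_intervals("c1", 1, 5), "-")   # "TACG"
#' @export
extract_sequence <- function(genome, interval, strand = "+") {
  stopifnot(nrow(interval) == 1L, strand %in% c("+", "-"))
  contig <- interval$contig
  if (!contig %in% names(genome))
    stop("unknown contig '", contig, "'")
  clen <- nchar(genome[[contig]])
  if (interval$start < 0 || interval$end > clen)
    stop("interval [", format_bp(interval$start), ", ",
         format_bp(interval$end), ") beyond bounds of contig '", contig,
         "' (length ", clen, ")")
  s <- substr(genome[[contig]], interval$start + 1L, interval$end)
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Write a motif-hit report
#'
#' Writes the retained sites as a tab-separated table with columns `Gene`,
#' `Location`, `Motif`, `Relative_score`, `Strand`, `Regulatory_Element`,
#' `TFs`. `Location` is `contig:start-end` in the same 0-based half-open
#' convention as BED. `Strand` is the hit's orientation relative to the
#' transcript sense (`+` sense, `-` antisense). The relative score is
#' rendered with 4 decimals as a fraction, or 2 decimals as a percentage.
#'
#' @param hits Motif-hit table (see [run_scan()]), or an `are_scan` object.
#' @param path Output file path or connection.
#' @param score_style `"fraction"` (default) or `"percent"`.
#' @return Number of data rows written.
#' @export
write_report <- function(hits, path, score_style = c("fraction", "percent")) {
  score_style <- match.arg(score_style)
  if (inherits(hits, "are_scan")) hits <- hits$hits
  header <- paste("Gene", "Location", "Motif", "Relative_score", "Strand",
                  "Regulatory_Element", "TFs", sep = "\t")
  if (nrow(hits) == 0L) {
    writeLines(header, path)
    return(0L)
  }
  score <- if (score_style == "percent") sprintf("%.2f", 100 * hits$relative)
           else sprintf("%.4f", hits$relative)
  re <- hits$regulatory_elements
  re[is.na(re) | !nzchar(re)] <- "."
  tfs <- vapply(strsplit(hits$tfs, ",", fixed = TRUE),
                function(x) paste(sort_labels(x), collapse = ","), "")
  rows <- paste(hits$gene,
                paste0(hits$contig, ":", format_bp(hits$start), "-",
                       format_bp(hits$end)),
                hits$motif, score, hits$relative_strand, re, tfs,
                sep = "\t")
  writeLines(c(header, rows), path)
  nrow(hits)
}
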