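test_that("interval construction enforces half-open invariants", {
  expect_error(genomic_intervals("c1", 200, 200), "start < end")
  expect_error(genomic_intervals("c1", -1, 5), "start < end")
  expect_error(genomic_intervals("", 1, 5), "empty contig")
  expect_silent(genomic_intervals("c1", 0, 1))
})

test_that("intersect_intervals reports half-open overlaps with clipped segments", {
  a <- genomic_intervals("c1", 100, 200)
  b <- genomic_intervals("c1", 150, 250)
  ov <- intersect_intervals(a, b)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$start, 150)
  expect_equal(ov$end, 200)

  # touching is not overlapping under half-open semantics
  expect_equal(nrow(intersect_intervals(a, genomic_intervals("c1", 200, 300))),
               0L)
  # different contigs never overlap
  expect_equal(nrow(intersect_intervals(a, genomic_intervals("c2", 100, 200))),
               0L)
})

test_that("intersect_intervals matches the brute-force all-pairs oracle", {
  set.seed(1)
  a <- random_intervals(200)
  b <- random_intervals(200)
  expect_equal(intersect_intervals(a, b), brute_overlap(a, b),
               ignore_attr = TRUE)
})

test_that("extend_upstream extends from the strand-dependent TSS and clamps", {
  tx <- transcripts("NM_1", "chr1", 10000, 12000, "+", gene = "g")
  w <- extend_upstream(tx, 5000, contig_length = 1e6)
  expect_equal(c(w$start, w$end), c(5000, 12000))

  tx_m <- transcripts("NM_2", "chr1", 10000, 12000, "-", gene = "g")
  w <- extend_upstream(tx_m, 5000, contig_length = 1e6)
  expect_equal(c(w$start, w$end), c(10000, 17000))

  tx_near <- transcripts("NM_3", "chr1", 2000, 4000, "+", gene = "g")
  w <- extend_upstream(tx_near, 5000, contig_length = 1e6)
  expect_equal(c(w$start, w$end), c(0, 4000))

  # clamp at contig end on the minus strand
  w <- extend_upstream(tx_m, 5000, contig_length = 13000)
  expect_equal(c(w$start, w$end), c(10000, 13000))

  expect_error(transcripts("NM_4", "chr1", 1, 10, "."), "strand")
})

test_that("extension preserves the transcript body and adds upstream_bp unless clamped", {
  set.seed(3)
  for (rep in 1:50) {
    s <- sample.int(20000, 1) + 6000
    e <- s + sample.int(3000, 1)
    tx <- transcripts("NM", "c1", s, e, sample(c("+", "-"), 1))
    up <- sample.int(5000, 1)
    w <- extend_upstream(tx, up, contig_length = 1e6)
    expect_true(w$start <= s && e <= w$end)
    expect_equal(w$end - w$start, (e - s) + up)
  }
})

test_that("build_search_regions composes windows and peaks, clips and dedupes", {
  tx <- transcripts("NM_1", "c1", 30, 35, "+", gene = "geneA")
  peaks <- list(NFE2L2 = genomic_intervals("c1", 8, 14))
  reg <- build_search_regions(tx, peaks, upstream_bp = 5000,
                              contig_lengths = c(c1 = 60))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$gene, "geneA")
  expect_equal(reg$tf, "NFE2L2")
  expect_equal(c(reg$start, reg$end), c(8, 14))  # window clamps to (0, 35)

  # peak outside the window yields nothing
  reg <- build_search_regions(tx, list(NFE2L2 = genomic_intervals("c1", 40, 50)),
                              upstream_bp = 5000,
                              contig_lengths = c(c1 = 60))
  expect_equal(nrow(reg), 0L)

  # duplicate peaks collapse to one region
  dup <- list(NFE2L2 = genomic_intervals(c("c1", "c1"), c(8, 8), c(14, 14)))
  reg <- build_search_regions(tx, dup, upstream_bp = 5000,
                              contig_lengths = c(c1 = 60))
  expect_equal(nrow(reg), 1L)

  # clipping off: the whole peak is kept even where it leaves the window
  tx2 <- transcripts("NM_2", "c1", 30, 35, "+", gene = "geneB")
  wide_peak <- list(NFE2L2 = genomic_intervals("c1", 20, 50))
  reg <- build_search_regions(tx2, wide_peak, upstream_bp = 5000,
                              contig_lengths = c(c1 = 100),
                              clip_to_window = FALSE)
  expect_equal(c(reg$start, reg$end), c(20, 50))
})

test_that("search regions are contained in both their peak and their window", {
  set.seed(9)
  for (rep in 1:10) {
    n_tx <- 5
    s <- sample.int(30000, n_tx) + 6000
    tx <- transcripts(paste0("NM_", 1:n_tx), "c1", s, s + 2000,
                      sample(c("+", "-"), n_tx, replace = TRUE),
                      gene = paste0("g", 1:n_tx))
    peaks <- list(TF1 = random_intervals(30, contigs = "c1",
                                         max_pos = 40000))
    reg <- build_search_regions(tx, peaks, upstream_bp = 5000,
                                contig_lengths = c(c1 = 50000))
    if (nrow(reg) == 0) next
    for (i in seq_len(nrow(reg))) {
      txi <- tx[tx$gene == reg$gene[i], ]
      w <- extend_upstream(txi, 5000, contig_length = 50000)
      expect_true(reg$start[i] >= w$start && reg$end[i] <= w$end)
      covered <- any(peaks$TF1$start <= reg$start[i] &
                     peaks$TF1$end >= reg$end[i])
      expect_true(covered)
    }
  }
})

test_that("segmentation annotation joins sorted unique overlapping labels", {
  hit <- data.frame(contig = "c1", start = 100, end = 111,
                    stringsAsFactors = FALSE)
  seg <- genomic_intervals("c1", 50, 150, label = "PLS")
  expect_equal(annotate_with_segmentation(hit, seg)$regulatory_elements,
               "PLS")
  seg_far <- genomic_intervals("c2", 0, 999, label = "dELS")
  expect_equal(annotate_with_segmentation(hit, seg_far)$regulatory_elements,
               ".")
  seg2 <- rbind(genomic_intervals("c1", 50, 150, label = "PLS"),
                genomic_intervals("c1", 105, 300, label = "dELS"),
                genomic_intervals("c1", 90, 200, label = "PLS"))
  expect_equal(annotate_with_segmentation(hit, seg2)$regulatory_elements,
               "dELS,PLS")
})
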