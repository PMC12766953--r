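# Scoring mathematics, verified against hand-derived values for the toy
# 2-position matrix: with pseudocount 1 and uniform background the cells
# are log2(((count + 1)/8)/0.25), i.e. position 1 (A=1, C=0, G=-1, T=-1)
# and position 2 (A=-1, C=-1, G=1, T=0).

test_that("pfm_to_pssm reproduces the hand-computed toy matrix", {
  pssm <- pfm_to_pssm(toy_counts())
  expect_equal(pssm$scores[, 1], c(A = 1, C = 0, G = -1, T = -1),
               tolerance = 1e-9)
  expect_equal(pssm$scores[, 2], c(A = -1, C = -1, G = 1, T = 0),
               tolerance = 1e-9)
  expect_equal(pssm$min_score, -2, tolerance = 1e-9)
  expect_equal(pssm$max_score, 2, tolerance = 1e-9)
})

test_that("pseudocounting keeps all scores finite despite zero counts", {
  set.seed(21)
  for (rep in 1:20) {
    counts <- random_pfm(sample(2:6, 1))
    counts[sample(length(counts), 3)] <- 0
    pssm <- tryCatch(pfm_to_pssm(counts), degenerate_profile = function(e) NULL)
    if (is.null(pssm)) next
    expect_true(all(is.finite(pssm$scores)))
  }
})

test_that("uniform profiles raise a degenerate_profile error", {
  uniform <- matrix(2, nrow = 4, ncol = 1,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(pfm_to_pssm(uniform), class = "degenerate_profile")
})

test_that("score_window sums per-position scores and flags non-ACGT windows", {
  pssm <- pfm_to_pssm(toy_counts())
  expect_equal(score_window(pssm, "AG"), 2, tolerance = 1e-9)
  expect_equal(score_window(pssm, "GA"), -2, tolerance = 1e-9)
  expect_true(is.na(score_window(pssm, "AN")))
  expect_error(score_window(pssm, "AGT"), "width")
})

test_that("relative_score rescales between min and max attainable scores", {
  pssm <- pfm_to_pssm(toy_counts())
  # all 16 windows of the toy matrix fall on the 0/0.25/0.5/0.75/1 grid
  expect_equal(relative_score(pssm, 2), 1)
  expect_equal(relative_score(pssm, -2), 0)
  expect_equal(relative_score(pssm, score_window(pssm, "AT")), 0.75)
  expect_equal(relative_score(pssm, score_window(pssm, "CG")), 0.75)
  expect_equal(relative_score(pssm, score_window(pssm, "CT")), 0.5)
  expect_equal(relative_score(pssm, score_window(pssm, "GT")), 0.25)
  # equivalence with the (x + |min|)/(|max| + |min|) form when min <= 0
  for (w in c("AG", "AT", "CT", "GT", "GA"))
    expect_equal(relative_score(pssm, score_window(pssm, w)),
                 (score_window(pssm, w) + abs(pssm$min_score)) /
                   (abs(pssm$max_score) + abs(pssm$min_score)),
                 tolerance = 1e-12)
})

test_that("reverse_complement complements, reverses, and is an involution", {
  expect_identical(reverse_complement("AG"), "CT")
  expect_identical(reverse_complement("CGTA"), "TACG")
  expect_identical(reverse_complement("NAT"), "ATN")
  expect_error(reverse_complement("AXG"), "ACGTN")
  set.seed(2)
  for (rep in 1:50) {
    s <- random_seq(sample.int(30, 1), alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("scan_sequence retains the hand-enumerated windows of AAGT", {
  pssm <- pfm_to_pssm(toy_counts())
  # forward windows: AA 0.5, AG 1.0, GT 0.25; reverse: TT 0.25, CT 0.5,
  # AC 0.5 -> only AG survives at 0.8
  hits <- scan_sequence(pssm, "AAGT", threshold = 0.8)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 1L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$matched, "AG")
  expect_equal(hits$absolute, 2, tolerance = 1e-9)
  expect_equal(hits$relative, 1, tolerance = 1e-9)
})

test_that("a site scoring exactly the threshold is kept, not discarded", {
  pssm <- pfm_to_pssm(toy_counts())
  expect_equal(nrow(scan_sequence(pssm, "AT", threshold = 0.75,
                                  strands = "plus_only")), 1L)
  expect_equal(nrow(scan_sequence(pssm, "AT", threshold = 0.8,
                                  strands = "plus_only")), 0L)
})

test_that("scanning degenerate inputs is safe", {
  pssm <- pfm_to_pssm(toy_counts())
  expect_equal(nrow(scan_sequence(pssm, "A")), 0L)  # shorter than width
  expect_error(scan_sequence(pssm, "ACGT", threshold = 1.2), "\\[0, 1\\]")
  hits <- scan_sequence(pssm, "ANGT", threshold = 0)
  expect_true(all(!grepl("N", hits$matched)))
  expect_true(attr(hits, "n_not_scorable") > 0)
})

test_that("scanner equals exhaustive direct-formula enumeration on random cases", {
  set.seed(100)
  for (case in 1:150) {
    counts <- random_pfm(sample(2:5, 1))
    pssm <- pfm_to_pssm(counts)
    L <- sample(ncol(counts):12, 1)
    s <- random_seq(L, alphabet = c("A", "C", "G", "T", "T", "A", "N"))
    t <- sample(c(0, 0.3, 0.8), 1)
    expect_equal(scan_sequence(pssm, s, threshold = t),
                 oracle_scan(counts, s, t),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("strand symmetry: minus hits mirror plus hits of the reverse complement", {
  set.seed(101)
  pssm <- pfm_to_pssm(toy_counts())
  for (rep in 1:100) {
    s <- random_seq(sample(2:20, 1))
    L <- nchar(s)
    fwd <- scan_sequence(pssm, s, threshold = 0.5)
    mirr <- scan_sequence(pssm, reverse_complement(s), threshold = 0.5)
    minus <- fwd[fwd$strand == "-", ]
    plus_of_rc <- mirr[mirr$strand == "+", ]
    expect_equal(sort(L - pssm$width - minus$offset),
                 sort(plus_of_rc$offset))
    m1 <- minus[order(minus$matched, minus$offset), ]
    m2 <- plus_of_rc[order(plus_of_rc$matched,
                           L - pssm$width - plus_of_rc$offset), ]
    expect_equal(m1$absolute, m2$absolute, tolerance = 1e-9)
    expect_equal(m1$relative, m2$relative, tolerance = 1e-9)
  }
})

test_that("raising the threshold never adds hits", {
  set.seed(102)
  counts <- random_pfm(4)
  pssm <- pfm_to_pssm(counts)
  s <- random_seq(200)
  key <- function(h) paste(h$offset, h$strand)
  prev <- scan_sequence(pssm, s, threshold = 0)
  for (t in c(0.2, 0.5, 0.8, 1)) {
    cur <- scan_sequence(pssm, s, threshold = t)
    expect_true(all(key(cur) %in% key(prev)))
    prev <- cur
  }
})

test_that("score bounds hold and the consensus/anti-consensus hit the extremes", {
  set.seed(103)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:20) {
    counts <- random_pfm(sample(2:6, 1))
    pssm <- pfm_to_pssm(counts)
    all_hits <- scan_sequence(pssm, random_seq(100), threshold = 0)
    expect_true(all(all_hits$absolute >= pssm$min_score - 1e-9))
    expect_true(all(all_hits$absolute <= pssm$max_score + 1e-9))
    expect_true(all(all_hits$relative >= 0 & all_hits$relative <= 1))
    best <- paste(bases[apply(pssm$scores, 2, which.max)], collapse = "")
    worst <- paste(bases[apply(pssm$scores, 2, which.min)], collapse = "")
    expect_equal(relative_score(pssm, score_window(pssm, best)), 1)
    expect_equal(relative_score(pssm, score_window(pssm, worst)), 0)
  }
})
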