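---
title: "Methods: ARE discovery by PSSM scanning of peak-supported promoter windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ARE discovery by PSSM scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arescan)
```

## The problem and the model

Antioxidant response elements (AREs) are short enhancer sequences bound
by NRF2/small-MAF dimers (and competed for by BACH1). Given a set of
genes of interest, `arescan` looks for putative AREs where two lines of
evidence meet: the DNA sequence resembles the binding preference encoded
in a position frequency matrix (PFM), and the location falls under a
ChIP-seq peak for one of the ARE-binding factors inside the gene's
regulatory span.

The procedure is deliberately simple and fully deterministic:

1. Each transcript interval is extended upstream of its transcription
   start site (TSS): a `+` transcript `[s, e)` becomes `[s - u, e)`, a
   `-` transcript becomes `[s, e + u)`, clamped to the contig. The
   transcript body is kept inside the window, so intragenic
   promoter-proximal sites are not lost.
2. Windows are intersected per transcription factor with its peak set;
   every peak-window overlap of at least 1 bp yields a search region.
   The scanned segment is the *clipped* overlap, which guarantees every
   reported site lies both under a peak and within the gene's regulatory
   span; `clip_to_window = FALSE` scans whole peaks instead for users who
   prefer the looser reading.
3. Region sequences are extracted from the genome and scanned with the
   PSSM on both strands (see below).
4. Retained sites are deduplicated across TFs (same gene, span, strand
   and sequence merge their TF labels), annotated with overlapping
   cCRE segmentation labels (PLS, dELS, ...), and reported per gene.

## Scoring mathematics

With counts $n(p, x)$ for base $x$ at motif position $p$, pseudocount
$c$ and background $b(x)$:

$$S(p, x) = \log_2 \frac{(n(p,x) + c) \,/\, \sum_y (n(p,y) + c)}{b(x)}$$

The absolute score of a window $w$ is $\sum_p S(p, w_p)$; with
$m = \sum_p \min_x S(p, x)$ and $M = \sum_p \max_x S(p, x)$ the relative
score is

$$\mathrm{rel}(w) = \frac{\mathrm{abs}(w) - m}{M - m} \in [0, 1].$$

Because pseudocounted column frequencies sum to one, the smallest column
frequency never exceeds a uniform background, so $m \le 0 \le M$ always
holds here; in that case this expression is identical to the equivalent
form $(\mathrm{abs}(w) + |m|) / (|M| + |m|)$, which the unit tests assert
cell by cell on a hand-computed toy matrix. For a hypothetical matrix
with $m > 0$ the implementation stays well-defined (it is simply the
min-max rescaling); this edge is documented rather than guessed around.

```{r toy}
counts <- matrix(c(3, 1, 0, 0, 0, 0, 3, 1), nrow = 4,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
pssm <- pfm_to_pssm(counts)   # cells are log2(((n+1)/8)/0.25)
pssm$scores
c(pssm$min_score, pssm$max_score)
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `upstream_bp` | 5000 bp | upstream extension of each transcript from its TSS |
| `threshold` | 0.8 | minimum relative score; a site scoring exactly 0.8 is **kept** ("below" is discarded) |
| `strands` | `both` | antisense AREs are real and reported with strand `-` relative to the transcript |
| `pseudocount` | 1 | added to every count before normalization, so no $\log 0$ |
| `background` | uniform 0.25 | the expected base frequency in the odds ratio; uniform is the JASPAR-style convention for relative scoring |
| `min_overlap` | 1 bp | the common interval-tool default for peak-window intersection |
| `clip_to_window` | `TRUE` | scan peak∩window overlaps rather than whole peaks |

## Numerical and policy choices

* **Coordinates** are 0-based half-open everywhere, including the
  report's `Location` column; touching intervals do not overlap.
* **Retention is `>= threshold`**, so boundary sites survive.
* **Windows containing `N`** (or any non-ACGT residue) are skipped and
  counted, not penalized — the matrix has no column for ambiguity codes.
* **Overlapping qualifying windows are all reported**; there is no greedy
  masking, since genes routinely carry several clustered sites.
* **Relative score clamping** to $[0,1]$ is applied only against
  floating-point drift (up to $10^{-12}$); scores can never leave the
  interval mathematically.
* **Motif orientation in the report** follows the transcript sense
  (antisense matches are reverse-complemented for display) so sense hits
  read like the ARE consensus; `genomic_orientation = TRUE` preserves the
  as-matched rendering.
* **Per-TF intersection** (rather than pooling all peaks) is used so each
  reported site can name the factors whose peaks support it; identical
  sites found under several TFs' peaks merge their labels.
* **Label ordering** (TF lists, segmentation classes) uses a
  locale-independent case-insensitive sort, so output is byte-identical
  across machines.
* **Degenerate profiles** (every column uniform, so $M = m$) raise a
  classed `degenerate_profile` error instead of returning undefined
  relative scores.

## What the synthetic generator emulates

`generate_dataset()` builds, from a single seed, the full input surface:
two 50 kb contigs of i.i.d. background sequence at a target GC of 0.5;
seven stranded transcripts (named after inflammasome/pyroptosis genes
purely as labels) laid out in non-overlapping window slots; three peaks
of 200–400 bp per factor for the five-TF panel, placed inside a promoter
window with probability 0.7; a PLS label over the 500 bp
promoter-proximal to each TSS and dELS labels over TSS-distal peak
cores; and ten planted motif instances — five exact consensus copies
(relative score 1 by construction) and five decoys mutated until their
oracle relative score drops below threshold. The decoy criterion is
applied to *both* orientations of the mutated sequence: the scanner scans
both strands, so a decoy whose reverse complement still scored above
threshold would be reported at the planted location and corrupt the
recovery accounting. Planted instances never overlap; placement resamples
up to 100 times and then fails loudly rather than silently dropping an
instance.

Truth scores are computed by a direct, separate evaluation of the count
matrix (`oracle_relative`), never by the scanner under test, and the test
suite carries a second, fully independent oracle implementation of
scanning, reverse complementation and all-pairs interval overlap.

What the generator does **not** emulate: real nucleotide composition
(isochores, CpG islands, repeats), ChIP-seq peak-shape statistics,
multiple transcripts per gene, or biologically meaningful positioning of
AREs. Passing recovery tests therefore demonstrates the correctness of
the machinery — coordinates, strands, scores, thresholds — not the
biological sensitivity or specificity of the 0.8 cutoff on real genomes.

## Problem sizes in the test suite

The suite verifies the scanner against exhaustive enumeration for
matrices of width up to 5 over sequences up to 12 bp (1000 random
cases), checks strand symmetry and involution on 1000 random sequences,
compares interval intersection with the naive all-pairs oracle on 1000
random instances, and runs full planted-motif recovery across 20 seeds
of the default 100 kb synthetic study — sizes chosen so the whole suite
exercises every code path while remaining a desk-scale computation.

## Known limitations

* Scores are not calibrated to p-values; the relative score is a
  min-max rescaling, and 0.8 is the inherited operating point, not an
  error-rate guarantee.
* The background model is zeroth-order (single-base frequencies); no
  dinucleotide or Markov background is offered.
* Genome access is plain FASTA held in memory — appropriate for the
  regulatory windows of a gene panel, not for whole-genome scans of
  large genomes (no faidx/2bit access).
* Peak sets are used as given; peaks from multiple experiments of the
  same factor are not merged before intersection (duplicate regions are
  deduplicated exactly, and identical hits merge downstream).
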