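#' GC content of a DNA sequence
#'
#' Counts G+C over unambiguous bases; `N` is excluded from both the
#' numerator and the denominator.
#'
#' @param seq single DNA string (character or DNAString).
#' @return list with `gc_count` (integer) and `fraction` (G+C over
#'   non-N length).
#' @export
gcContent <- function(seq) {
  s <- toupper(as.character(seq)[1L])
  .checkAlphabet(list(s), "dna")
  chars <- strsplit(s, "")[[1L]]
  n <- sum(chars != "N")
  if (n == 0L) stop("empty or all-N sequence")
  gc <- sum(chars %in% c("G", "C"))
  list(gc_count = as.integer(gc), fraction = gc / n)
}

#' Pearson chi-square test of GC content against an expected fraction
#'
#' One-degree-of-freedom test of the observed (GC, AT) counts against
#' the expectation `(p*n, (1-p)*n)`:
#' \eqn{\chi^2 = (gc - np)^2 / (np(1-p))}, with the p-value from the
#' chi-square(1) distribution. Warns when an expected count falls below
#' 1 (the asymptotic test is unreliable there).
#'
#' @param gc_count observed G+C count.
#' @param length_nt number of unambiguous bases.
#' @param expected_p expected GC fraction in (0, 1).
#' @return list with `chi_square` and `p_value`.
#' @export
gcChiSquare <- function(gc_count, length_nt, expected_p) {
  stopifnot(length_nt > 0, expected_p > 0, expected_p < 1,
            gc_count >= 0, gc_count <= length_nt)
  e_gc <- length_nt * expected_p
  e_at <- length_nt * (1 - expected_p)
  if (min(e_gc, e_at) < 1)
    warning("expected count below 1; chi-square approximation unreliable")
  chi <- (gc_count - e_gc)^2 / (e_gc * e_at / length_nt)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE))
}

#' Screen coding sequences for anomalous GC composition
#'
#' Compares each gene's GC content to the genome-average coding GC with
#' [gcChiSquare()]; genes whose composition deviates at `alpha` are
#' flagged as candidate horizontal acquisitions. Composition is a
#' coarse HGT signal: recently transferred genes tend to retain the
#' donor's base composition.
#'
#' @param genes named character vector or DNAStringSet of CDSs
#'   (annotated start through stop codon).
#' @param genomeAvgGC genome-average coding GC fraction (default 0.59).
#' @param alpha significance level for the flag (default 0.01).
#' @return [S4Vectors::DataFrame] with columns `locus`, `length_nt`,
#'   `gc_count`, `gc_percent`, `expected_gc_fraction`, `chi_square`,
#'   `p_value`, `hgt_flag`.
#' @export
hgtScreen <- function(genes, genomeAvgGC = 0.59, alpha = 0.01) {
  loci <- names(genes)
  if (is.null(loci)) stop("genes must be named by locus")
  rows <- lapply(loci, function(locus) {
    s <- toupper(as.character(genes[[locus]]))
    .checkAlphabet(list(s), "dna")
    chars <- strsplit(s, "")[[1L]]
    n <- sum(chars != "N")
    if (n == 0L) stop("empty or all-N sequence for ", locus)
    gc <- sum(chars %in% c("G", "C"))
    chi <- gcChiSquare(gc, n, genomeAvgGC)
    data.frame(locus = locus, length_nt = n, gc_count = gc,
               gc_percent = 100 * gc / n,
               expected_gc_fraction = genomeAvgGC,
               chi_square = chi$chi_square, p_value = chi$p_value,
               hgt_flag = chi$p_value < alpha)
  })
  DataFrame(do.call(rbind, rows))
}

#' Genome-average coding GC fraction
#'
#' Pools G+C and unambiguous-base counts over a CDS collection; use to
#' recompute the background for [hgtScreen()] from a genome-wide CDS
#' FASTA instead of the published average.
#'
#' @param cds character vector or DNAStringSet of coding sequences.
#' @return pooled GC fraction.
#' @export
codingGC <- function(cds) {
  seqs <- toupper(as.character(cds))
  gc <- 0; n <- 0
  for (s in seqs) {
    chars <- strsplit(s, "")[[1L]]
    gc <- gc + sum(chars %in% c("G", "C"))
    n <- n + sum(chars != "N")
  }
  if (n == 0L) stop("no unambiguous bases")
  gc / n
}
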