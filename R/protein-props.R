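# Average (isotope-weighted) residue masses in Da, Expasy convention;
# a peptide's mass is the residue sum plus one water (18.0153 Da).
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# Bjellqvist pKa set (the ProtParam convention): side chains, default
# termini, and residue-specific terminal corrections.
PK_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PK_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PK_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36,
                         T = 6.82, V = 7.44, E = 7.7)
PK_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

.aaChars <- function(protein) {
  p <- toupper(as.character(protein)[1L])
  if (nchar(p) == 0L) stop("empty protein sequence")
  chars <- strsplit(p, "")[[1L]]
  bad <- which(!(chars %in% names(AA_RESIDUE_MASS)))
  if (length(bad))
    stop("unknown residue '", chars[bad[1L]], "' at position ", bad[1L])
  chars
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses (Expasy table, fixed in
#' `AA_RESIDUE_MASS`) plus one water mass of 18.0153 Da. Ambiguity
#' codes are rejected.
#'
#' @param protein amino-acid string over the 20 standard residues.
#' @return molecular weight in Da.
#' @export
molecularWeight <- function(protein) {
  sum(AA_RESIDUE_MASS[.aaChars(protein)]) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch charge over the N-terminus, C-terminus and the
#' ionisable side chains (D, E, C, Y, H, K, R) with the Bjellqvist pKa
#' set, including its residue-specific terminal pKa corrections.
#' Strictly decreasing in pH.
#'
#' @param protein amino-acid string.
#' @param pH pH value(s).
#' @return net charge (vectorised over `pH`).
#' @export
netCharge <- function(protein, pH) {
  chars <- .aaChars(protein)
  first <- chars[1L]; last <- chars[length(chars)]
  pos <- c(Nterm = unname(
    if (first %in% names(PK_NTERM_BY_RESIDUE)) PK_NTERM_BY_RESIDUE[first]
    else PK_POSITIVE[["Nterm"]]))
  for (aa in c("K", "R", "H")) {
    k <- sum(chars == aa)
    if (k) pos <- c(pos, rep(PK_POSITIVE[[aa]], k))
  }
  neg <- c(Cterm = unname(
    if (last %in% names(PK_CTERM_BY_RESIDUE)) PK_CTERM_BY_RESIDUE[last]
    else PK_NEGATIVE[["Cterm"]]))
  for (aa in c("D", "E", "C", "Y")) {
    k <- sum(chars == aa)
    if (k) neg <- c(neg, rep(PK_NEGATIVE[[aa]], k))
  }
  vapply(pH, function(ph) {
    sum(1 / (1 + 10^(ph - pos))) - sum(1 / (1 + 10^(neg - ph)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which [netCharge()] is zero, located by bisection on
#' [0, 14] to a tolerance of 1e-4 pH units; the charge function is
#' strictly monotone so the root is unique.
#'
#' @param protein amino-acid string.
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(protein) {
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (netCharge(protein, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical properties of a protein collection
#'
#' @param proteins named character vector or AAStringSet.
#' @return [S4Vectors::DataFrame] with `locus`, `length_aa`, `mw_da`,
#'   `pi`.
#' @export
proteinProperties <- function(proteins) {
  loci <- names(proteins)
  if (is.null(loci)) stop("proteins must be named by locus")
  rows <- lapply(loci, function(locus) {
    p <- toupper(as.character(proteins[[locus]]))
    data.frame(locus = locus, length_aa = nchar(p),
               mw_da = molecularWeight(p), pi = isoelectricPoint(p))
  })
  DataFrame(do.call(rbind, rows))
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise identity and similarity of two proteins
#'
#' Needleman-Wunsch global alignment via
#' [Biostrings::pairwiseAlignment()] with BLOSUM62 scoring, gap opening
#' 10 and gap extension 0.5. Identity is the fraction of alignment
#' columns (gaps included in the denominator) with identical residues;
#' similarity additionally counts columns whose residue pair has a
#' positive BLOSUM62 score.
#'
#' @param a,b amino-acid strings.
#' @param locus_a,locus_b optional labels for the report.
#' @return one-row data.frame with `locus_a`, `locus_b`,
#'   `identity_pct`, `similarity_pct` (percentages of alignment
#'   columns), `alignment_length`.
#' @export
pairwiseIdentitySimilarity <- function(a, b, locus_a = "a", locus_b = "b") {
  a <- paste(.aaChars(a), collapse = "")
  b <- paste(.aaChars(b), collapse = "")
  mat <- .blosum62()
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  ncols <- length(pa)
  both <- pa != "-" & pb != "-"
  ident <- sum(both & pa == pb)
  simil <- sum(mat[cbind(pa[both], pb[both])] > 0)
  data.frame(locus_a = locus_a, locus_b = locus_b,
             identity_pct = 100 * ident / ncols,
             similarity_pct = 100 * simil / ncols,
             alignment_length = ncols)
}

#' All pairwise identities/similarities in a protein collection
#'
#' @param proteins named character vector or AAStringSet.
#' @return data.frame with one row per unordered pair.
#' @export
proteinSimilarityTable <- function(proteins) {
  loci <- names(proteins)
  if (is.null(loci) || length(loci) < 2L)
    stop("need at least two named proteins")
  pairs <- utils::combn(loci, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    la <- pairs[1L, i]; lb <- pairs[2L, i]
    pairwiseIdentitySimilarity(
      as.character(proteins[[la]]), as.character(proteins[[lb]]), la, lb)
  })
  do.call(rbind, rows)
}
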