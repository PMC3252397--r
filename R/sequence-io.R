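#' @importFrom Biostrings readBStringSet DNAStringSet AAStringSet
#'   writeXStringSet reverseComplement translate getGeneticCode DNAString
#'   matchPattern
#' @importFrom BiocGenerics start
NULL

.checkAlphabet <- function(seqs, alphabet) {
  allowed <- if (alphabet == "dna") "ACGTN" else "ACDEFGHIKLMNPQRSTVWY"
  pat <- sprintf("[^%s]", allowed)
  ids <- names(seqs)
  if (is.null(ids)) ids <- rep("", length(seqs))
  for (i in seq_along(seqs)) {
    bad <- regexpr(pat, seqs[[i]])
    if (bad > 0L)
      stop(sprintf(
        "illegal %s character '%s' at position %d%s",
        alphabet, substr(seqs[[i]], bad, bad), bad,
        if (nzchar(ids[i])) sprintf(" in record '%s'", ids[i]) else ""
      ))
  }
  invisible(TRUE)
}

#' Read a FASTA file with strict validation
#'
#' Wraps [Biostrings::readBStringSet()] with the checks the downstream
#' analyses rely on: records are uppercased, ids must be unique, and
#' every character must belong to the declared alphabet (`ACGTN` for
#' DNA, the 20 standard residues for protein).
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet],
#'   one record per header, file order preserved, names set to the
#'   first whitespace-delimited token of each header.
#' @export
readSequences <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  raw <- readBStringSet(path)
  if (length(raw) == 0L)
    stop("no FASTA records in ", path)
  seqs <- toupper(as.character(raw))
  names(seqs) <- sub("\\s.*$", "", names(raw))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id(s): ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  .checkAlphabet(seqs, alphabet)
  if (alphabet == "dna") DNAStringSet(seqs) else AAStringSet(seqs)
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param x a named character vector or XStringSet.
#' @param path output path.
#' @export
writeSequences <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  writeXStringSet(x, path, width = 60L)
}

#' Read a gene coordinate table
#'
#' Tab-separated with header `locus replicon start end strand`;
#' coordinates are 1-based inclusive, strand `+` or `-` (GenBank
#' convention).
#'
#' @param path path to the TSV file.
#' @return data.frame with the five columns, types checked.
#' @export
readCoordinates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "replicon", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("coordinate table must have columns: ", paste(need, collapse = " "))
  if (any(tab$start < 1L) || any(tab$start > tab$end))
    stop("need 1 <= start <= end for every row")
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  tab[need]
}

#' Read a qPCR primer table
#'
#' Tab-separated with header `gene forward reverse expected_amplicon_bp`
#' (the last column optional).
#'
#' @param path path to the TSV file.
#' @return data.frame of primer pairs.
#' @export
readPrimerTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "forward", "reverse")
  if (!all(need %in% names(tab)))
    stop("primer table must have columns: ", paste(need, collapse = " "))
  tab$forward <- toupper(tab$forward)
  tab$reverse <- toupper(tab$reverse)
  .checkAlphabet(as.list(c(tab$forward, tab$reverse)), "dna")
  if (any(nchar(tab$forward) < 10L) || any(nchar(tab$reverse) < 10L))
    stop("primers must be at least 10 nt long")
  tab
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Thin validating
#' wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character strings as plain character strings.
#'
#' @param seq a single DNA string (A/C/G/T/N, case-insensitive).
#' @return the reverse complement, uppercase character.
#' @export
revcomp <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  .checkAlphabet(list(seq), "dna")
  as.character(reverseComplement(DNAString(seq)))
}

#' Translate a bacterial coding sequence
#'
#' Uses the bacterial/archaeal genetic code (NCBI table 11). A single
#' trailing stop codon is trimmed; an internal stop is an error. The
#' first codon is reported as `M` when it is one of the table-11
#' initiators ATG/GTG/TTG (with a message for the non-ATG ones);
#' a non-initiator first codon triggers a warning and is translated
#' as written.
#'
#' @param seq a single DNA string, length divisible by 3.
#' @return single-letter amino-acid string.
#' @export
translateCDS <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  .checkAlphabet(list(seq), "dna")
  if (nchar(seq) %% 3L != 0L)
    stop("CDS length ", nchar(seq), " is not divisible by 3")
  if (grepl("N", seq, fixed = TRUE))
    stop("cannot translate ambiguous base N")
  aa <- as.character(translate(DNAString(seq),
                               genetic.code = getGeneticCode("11")))
  n <- nchar(aa)
  if (substr(aa, n, n) == "*") {
    aa <- substr(aa, 1L, n - 1L)
    n <- n - 1L
  }
  if (grepl("*", aa, fixed = TRUE))
    stop("internal stop codon at codon ",
         regexpr("*", aa, fixed = TRUE)[1L])
  first <- substr(seq, 1L, 3L)
  if (first %in% c("GTG", "TTG")) {
    message("initiator codon ", first, " reported as M")
    aa <- paste0("M", substr(aa, 2L, n))
  } else if (first != "ATG") {
    warning("first codon ", first, " is not a table-11 start codon")
  }
  aa
}

#' Extract the upstream region of a gene in coding orientation
#'
#' Returns the `n` bases immediately 5' of the first base of the start
#' codon. For minus-strand genes the region downstream of `end` on the
#' reference is taken and reverse-complemented, so the result always
#' reads toward the start codon. When the replicon boundary leaves
#' fewer than `n` bases the truncated region is returned with
#' attribute `truncated = TRUE`.
#'
#' @param genome single reference sequence (character or DNAString(Set)
#'   element) the coordinates refer to.
#' @param coords one-row data.frame (or list) with `start`, `end`,
#'   `strand` as in [readCoordinates()].
#' @param n window length in bases (default 200).
#' @return character string of length `min(n, available)`, with
#'   attribute `truncated` (logical).
#' @export
extractUpstream <- function(genome, coords, n = 200L) {
  g <- toupper(as.character(genome)[1L])
  L <- nchar(g)
  start <- as.integer(coords$start)
  end <- as.integer(coords$end)
  strand <- as.character(coords$strand)
  if (is.na(start) || is.na(end) || start < 1L || end > L || start > end)
    stop("coordinates [", start, ", ", end, "] outside genome of length ", L)
  if (strand == "+") {
    from <- max(1L, start - n)
    out <- substr(g, from, start - 1L)
    truncated <- (start - 1L) < n
  } else if (strand == "-") {
    to <- min(L, end + n)
    out <- revcomp(substr(g, end + 1L, to))
    truncated <- (L - end) < n
  } else stop("strand must be '+' or '-'")
  if (nchar(out) == 0L)
    stop("gene abuts the replicon boundary: no upstream bases")
  attr(out, "truncated") <- truncated
  out
}

.matchStarts <- function(pattern, subject) {
  # exact-match start positions, overlap-tolerant
  as.integer(start(matchPattern(pattern, DNAString(subject))))
}

#' In-silico PCR: locate the amplicon of a primer pair
#'
#' Searches both strands of the template for an exact match of the
#' forward primer followed downstream by the reverse complement of the
#' reverse primer. The amplicon length counts both primer footprints
#' inclusively, as gel-estimated product sizes do.
#'
#' @param template single DNA string (character or DNAString).
#' @param forward,reverse primer sequences written 5' to 3'.
#' @return amplicon length in bp, with attributes `strand` and
#'   `start` (1-based position of the forward-primer match on the
#'   matched strand); `NA` when no productive pair exists.
#'   More than one productive amplicon is an error (non-specific
#'   primers), listing every site found.
#' @export
findAmplicon <- function(template, forward, reverse) {
  tpl <- toupper(as.character(template)[1L])
  forward <- toupper(forward); reverse <- toupper(reverse)
  .checkAlphabet(list(tpl, forward, reverse), "dna")
  hits <- data.frame(strand = character(), start = integer(),
                     length = integer())
  for (strand in c("+", "-")) {
    s <- if (strand == "+") tpl else revcomp(tpl)
    f <- .matchStarts(forward, s)
    r <- .matchStarts(revcomp(reverse), s)
    for (fs in f) {
      ok <- r[r >= fs + nchar(forward)]
      for (rs in ok) {
        hits <- rbind(hits, data.frame(
          strand = strand, start = fs,
          length = rs + nchar(reverse) - fs
        ))
      }
    }
  }
  if (nrow(hits) == 0L) return(NA_integer_)
  if (nrow(hits) > 1L)
    stop("primers are non-specific: ", nrow(hits), " productive amplicons (",
         paste(sprintf("%s:%d:%dbp", hits$strand, hits$start, hits$length),
               collapse = ", "), ")")
  out <- hits$length[1L]
  attr(out, "strand") <- hits$strand[1L]
  attr(out, "start") <- hits$start[1L]
  out
}
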