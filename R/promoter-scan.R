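#' Uniform and GC-parameterised background compositions
#'
#' `gcBackground(gc)` places probability `gc/2` on each of G and C and
#' `(1-gc)/2` on each of A and T, matching an i.i.d. background of the
#' given genomic GC fraction. `uniformBackground()` is the equiprobable
#' composition under which log-odds scores coincide with Schneider-style
#' information in bits.
#'
#' @param gc GC fraction in (0, 1).
#' @return named numeric vector over A, C, G, T summing to 1.
#' @export
gcBackground <- function(gc) {
  stopifnot(gc > 0, gc < 1)
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

#' @rdname gcBackground
#' @export
uniformBackground <- function() c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

.siteMatrix <- function(sites) {
  sites <- toupper(as.character(sites))
  w <- unique(nchar(sites))
  if (length(sites) == 0L) stop("empty site list")
  if (length(w) != 1L) stop("sites have unequal widths: ",
                            paste(sort(w), collapse = ", "))
  m <- matrix(unlist(strsplit(sites, "")), nrow = length(sites),
              ncol = w, byrow = TRUE)
  if (!all(m %in% DNA_BASES))
    stop("training sites must contain only A, C, G, T")
  m
}

#' Build a positional weight matrix from aligned sites
#'
#' Per-position base counts are smoothed with a pseudocount and
#' normalised: \eqn{p_{l,b} = (n_{l,b} + c) / (N + 4c)}. The default
#' pseudocount of 0.5 per base keeps log-odds scores finite for bases
#' unseen in a small training set (here typically N = 18 sites).
#'
#' @param sites character vector (or DNAStringSet) of equal-length
#'   DNA strings.
#' @param pseudocount non-negative smoothing constant per base.
#' @param background named base-composition vector, e.g.
#'   [uniformBackground()] (default) or [gcBackground()].
#' @return a [PositionWeightMatrix-class].
#' @export
buildPWM <- function(sites, pseudocount = 0.5,
                     background = uniformBackground()) {
  m <- .siteMatrix(sites)
  counts <- vapply(seq_len(ncol(m)), function(l)
    vapply(DNA_BASES, function(b) sum(m[, l] == b), numeric(1)),
    numeric(4))
  counts <- matrix(counts, nrow = 4L,
                   dimnames = list(DNA_BASES, NULL))
  probs <- (counts + pseudocount) / (nrow(m) + 4 * pseudocount)
  new("PositionWeightMatrix", probs = probs, counts = counts,
      pseudocount = pseudocount, background = background[DNA_BASES])
}

#' Total information content (Rsequence) of a motif model
#'
#' \eqn{R_{sequence} = \sum_l \sum_b p_{l,b} \log_2(p_{l,b}/q_b)} with
#' \eqn{0 \log 0 \equiv 0}. Against an equiprobable background this is
#' \eqn{\sum_l (2 - H_l)} bits, i.e. 0 for a uniform matrix and 2 bits
#' per position for a one-hot matrix.
#'
#' @param x a [PositionWeightMatrix-class].
#' @return information content in bits.
#' @export
informationContent <- function(x) {
  p <- x@probs
  q <- x@background
  terms <- p * log2(sweep(p, 1L, q, "/"))
  sum(terms[p > 0])
}

#' Individual information (Ri) of one site under a motif model
#'
#' \eqn{R_i = \sum_l \log_2(p_{l, s_l}/q_{s_l})} bits: the log-odds
#' score of the site in bits. The consensus site maximises it; bases
#' absent from the training set score negatively (finite only when the
#' matrix was built with a positive pseudocount).
#'
#' @param x a [PositionWeightMatrix-class].
#' @param site DNA string of length `pwmWidth(x)`.
#' @param background optional composition overriding the matrix's own
#'   (used e.g. to rescore under a genome-GC background).
#' @return score in bits (may be `-Inf` for pseudocount 0).
#' @export
siteInformation <- function(x, site, background = NULL) {
  site <- toupper(as.character(site))
  stopifnot(length(site) == 1L)
  if (nchar(site) != pwmWidth(x))
    stop("site width ", nchar(site), " != matrix width ", pwmWidth(x))
  b <- strsplit(site, "")[[1L]]
  if (!all(b %in% DNA_BASES)) stop("site must contain only A, C, G, T")
  q <- if (is.null(background)) x@background else background
  sum(log2(x@probs[cbind(match(b, DNA_BASES), seq_along(b))] / q[b]))
}

#' Read a promoter training set
#'
#' Tab-separated with header `site35 spacer_len site10`: a 6-nt -35
#' element, the observed spacer length, and an 8-nt -10 element per row.
#'
#' @param path path to the TSV file.
#' @return data.frame usable by [fitSigma32Model()].
#' @export
readTrainingSet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site35", "spacer_len", "site10")
  if (!all(need %in% names(tab)))
    stop("training set must have columns: ", paste(need, collapse = " "))
  .validateTrainingSet(tab)
  tab[need]
}

.validateTrainingSet <- function(ts) {
  if (nrow(ts) < 2L) stop("training set needs at least 2 records")
  if (!all(nchar(ts$site35) == 6L)) stop("every site35 must be 6 nt")
  if (!all(nchar(ts$site10) == 8L)) stop("every site10 must be 8 nt")
  if (any(ts$spacer_len < 0L)) stop("spacer lengths must be non-negative")
  invisible(TRUE)
}

#' Fit a bipartite sigma-32 promoter model from a training set
#'
#' Builds one PWM from the aligned -35 hexamers and one from the
#' aligned -10 octamers; the admissible spacer range is the observed
#' minimum and maximum spacer length in the training set.
#'
#' @param ts training set data.frame (see [readTrainingSet()]).
#' @inheritParams buildPWM
#' @return a [SigmaPromoterModel-class].
#' @export
fitSigma32Model <- function(ts, pseudocount = 0.5,
                            background = uniformBackground()) {
  .validateTrainingSet(ts)
  new("SigmaPromoterModel",
      pwm35 = buildPWM(ts$site35, pseudocount, background),
      pwm10 = buildPWM(ts$site10, pseudocount, background),
      spacerMin = as.integer(min(ts$spacer_len)),
      spacerMax = as.integer(max(ts$spacer_len)))
}

.slidingScores <- function(pwm, chars) {
  # log-odds (bits) of every window of width w over a character vector
  w <- ncol(pwm@probs)
  L <- length(chars)
  if (L < w) return(numeric(0))
  lo <- log2(sweep(pwm@probs, 1L, pwm@background, "/"))
  idx <- match(chars, DNA_BASES)
  out <- numeric(L - w + 1L)
  for (l in seq_len(w))
    out <- out + lo[cbind(idx[l:(L - w + l)], l)]
  out
}

#' Scan an upstream window for bipartite sigma-32 promoter sites
#'
#' Enumerates every placement of the 6-bp -35 block and 8-bp -10 block
#' with a spacer inside the model's admissible range and both blocks
#' inside the window. Each placement is scored as the sum of the two
#' block log-odds scores in bits; the spacer length itself carries no
#' penalty. All placements are returned, best first; ties are broken
#' by proximity to the start codon, then by leftmost -35 position, so
#' the ordering is deterministic.
#'
#' @param model a [SigmaPromoterModel-class].
#' @param window upstream sequence in coding orientation, its last base
#'   immediately preceding the start codon (character or DNAString).
#' @return [S4Vectors::DataFrame] with columns `pos35`, `seq35`,
#'   `score35`, `bits35`, `spacer_len`, `pos10`, `seq10`, `score10`,
#'   `bits10`, `total_score`, `total_bits`, `dist_to_start` (bases
#'   between the end of the -10 block and the start codon). Positions
#'   are 1-based within the window.
#' @export
scanUpstream <- function(model, window) {
  win <- toupper(as.character(window)[1L])
  L <- nchar(win)
  smin <- model@spacerMin; smax <- model@spacerMax
  if (L < 14L + smin)
    stop("window length ", L, " below the minimal promoter footprint ",
         14L + smin)
  chars <- strsplit(win, "")[[1L]]
  if (!all(chars %in% DNA_BASES))
    stop("window must contain only A, C, G, T")
  s35 <- .slidingScores(model@pwm35, chars)
  s10 <- .slidingScores(model@pwm10, chars)
  rows <- vector("list", smax - smin + 1L)
  for (sp in smin:smax) {
    maxPos <- L - 13L - sp
    if (maxPos < 1L) next
    pos35 <- seq_len(maxPos)
    pos10 <- pos35 + 6L + sp
    rows[[sp - smin + 1L]] <- data.frame(
      pos35 = pos35, spacer_len = sp, pos10 = pos10,
      score35 = s35[pos35], score10 = s10[pos10]
    )
  }
  hits <- do.call(rbind, rows)
  hits$seq35 <- substring(win, hits$pos35, hits$pos35 + 5L)
  hits$seq10 <- substring(win, hits$pos10, hits$pos10 + 7L)
  hits$total_score <- hits$score35 + hits$score10
  hits$dist_to_start <- L - (hits$pos10 + 7L)
  hits <- hits[order(-hits$total_score, hits$dist_to_start, hits$pos35), ]
  DataFrame(
    pos35 = hits$pos35, seq35 = hits$seq35,
    score35 = hits$score35, bits35 = hits$score35,
    spacer_len = hits$spacer_len,
    pos10 = hits$pos10, seq10 = hits$seq10,
    score10 = hits$score10, bits10 = hits$score10,
    total_score = hits$total_score, total_bits = hits$total_score,
    dist_to_start = hits$dist_to_start
  )
}

#' Report the best promoter candidates for a set of genes
#'
#' Runs [scanUpstream()] on each upstream window and keeps the `topK`
#' hits per gene, adding the position of the -35 block relative to the
#' start codon as a negative offset (`offset_from_ATG`; -1 is the base
#' immediately before the A of ATG).
#'
#' @param model a [SigmaPromoterModel-class].
#' @param windows named character vector or DNAStringSet of upstream
#'   windows in coding orientation.
#' @param topK hits to keep per gene (default 1).
#' @return data.frame, TSV-ready, one block of rows per gene.
#' @export
reportPromoters <- function(model, windows, topK = 1L) {
  loci <- names(windows)
  if (is.null(loci)) stop("windows must be named by locus")
  out <- lapply(loci, function(locus) {
    hits <- as.data.frame(scanUpstream(model, windows[[locus]]))
    hits <- utils::head(hits, topK)
    L <- nchar(as.character(windows[[locus]]))
    cbind(locus = locus, hits,
          offset_from_ATG = hits$pos35 - L - 1L)
  })
  do.call(rbind, out)
}
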