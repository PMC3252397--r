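# Named PRNG streams: each generator draws from its own deterministic
# stream derived from (seed, stream name), so adding a generator to a
# workflow never perturbs the draws of existing ones. The caller's RNG
# state is saved and restored.
streamSeed <- function(seed, stream) {
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 1048573) * 2027 + h) %% 2147483647L
}

withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(streamSeed(seed, stream))
  force(expr)
}

.randomDNA <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate an aligned sigma-32 promoter training set
#'
#' Emulates a curated collection of aligned heat-shock promoters: each
#' record is the consensus pair with independent per-base mutations at
#' `mutationRate` (a mutation always changes the base, drawn uniformly
#' from the three alternatives) and a spacer length drawn uniformly
#' from `spacerRange`. The default of 18 sites mirrors the size of
#' curated bacterial sigma-32 training sets.
#'
#' @param consensus35 6-nt consensus of the -35 element.
#' @param consensus10 8-nt consensus of the -10 element.
#' @param n number of sites (default 18).
#' @param mutationRate per-base mutation probability in [0, 1].
#' @param spacerRange inclusive `c(min, max)` spacer lengths.
#' @param seed integer seed (named stream `"training_set"`).
#' @return data.frame with columns `site35`, `spacer_len`, `site10`,
#'   directly usable by [fitSigma32Model()].
#' @export
simulateTrainingSet <- function(consensus35 = "CTTGAA",
                                consensus10 = "CCCCATAT",
                                n = 18L, mutationRate = 0.1,
                                spacerRange = c(11L, 15L), seed = 1L) {
  stopifnot(nchar(consensus35) == 6L, nchar(consensus10) == 8L,
            mutationRate >= 0, mutationRate <= 1, n >= 2L)
  mutate <- function(site) {
    chars <- strsplit(site, "")[[1L]]
    hit <- stats::runif(length(chars)) < mutationRate
    for (i in which(hit))
      chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    paste(chars, collapse = "")
  }
  withStream(seed, "training_set", {
    data.frame(
      site35 = vapply(seq_len(n), function(i) mutate(consensus35),
                      character(1)),
      spacer_len = sample(seq(spacerRange[1L], spacerRange[2L]), n,
                          replace = TRUE),
      site10 = vapply(seq_len(n), function(i) mutate(consensus10),
                      character(1))
    )
  })
}

#' Simulate an upstream window, optionally with a planted promoter
#'
#' Draws an i.i.d. background sequence at the given GC fraction; when
#' `planted`, the consensus -35 and -10 boxes are written at a random
#' admissible position with a spacer drawn from `spacerRange`, and the
#' ground-truth placement is returned alongside.
#'
#' @inheritParams simulateTrainingSet
#' @param planted write the consensus boxes into the window?
#' @param upstreamLen window length in bases (default 200).
#' @param gc background GC fraction (default 0.5).
#' @param seed integer seed (named stream `"upstream"`).
#' @return list with `seq` (character window) and `truth` (list with
#'   `pos35`, `pos10`, `spacer_len`, or `NULL` when nothing planted).
#' @export
simulateUpstream <- function(consensus35 = "CTTGAA",
                             consensus10 = "CCCCATAT",
                             planted = TRUE, upstreamLen = 200L,
                             gc = 0.5, spacerRange = c(11L, 15L),
                             seed = 1L) {
  stopifnot(upstreamLen >= 14L + spacerRange[1L])
  withStream(seed, "upstream", {
    win <- .randomDNA(upstreamLen, gc)
    truth <- NULL
    if (planted) {
      sp <- sample(seq(spacerRange[1L], spacerRange[2L]), 1L)
      maxPos <- upstreamLen - 13L - sp
      pos35 <- sample.int(maxPos, 1L)
      pos10 <- pos35 + 6L + sp
      substr(win, pos35, pos35 + 5L) <- consensus35
      substr(win, pos10, pos10 + 7L) <- consensus10
      truth <- list(pos35 = pos35, pos10 = pos10, spacer_len = sp)
    }
    list(seq = win, truth = truth)
  })
}

#' Simulate a gene sequence with a target GC fraction
#'
#' I.i.d. bases with \eqn{P(G) + P(C)} equal to `gcTarget`; the
#' realised GC content fluctuates binomially around the target.
#'
#' @param lengthNt sequence length in bases.
#' @param gcTarget target GC fraction in [0, 1].
#' @param seed integer seed (named stream `"gene"`).
#' @return character DNA string.
#' @export
simulateGene <- function(lengthNt, gcTarget, seed = 1L) {
  if (gcTarget < 0 || gcTarget > 1)
    stop("gcTarget must be within [0, 1]")
  withStream(seed, "gene", .randomDNA(lengthNt, gcTarget))
}

#' Default heat-shock experimental design for the Ct simulator
#'
#' Three sHSP target genes plus the alaS endogenous control, a 30 degC
#' control condition and heat-shock samplings at 15, 30 and 60 min.
#' True folds rise over the time course; at 60 min they are 40, 3.478
#' and 2, so the strongest responder sits 20-fold above the weakest and
#' 11.5-fold above the intermediate one.
#'
#' @return data.frame with columns `gene`, `condition`, `fold`.
#' @export
defaultHeatShockDesign <- function() {
  genes <- c("Afe_1009", "Afe_1437", "Afe_2172")
  folds <- rbind(
    hs_15min = c(1.5, 6, 1.2),
    hs_30min = c(2.5, 18, 1.6),
    hs_60min = c(40 / 11.5, 40, 2)
  )
  colnames(folds) <- genes
  out <- expand.grid(gene = genes, condition = rownames(folds),
                     stringsAsFactors = FALSE)
  out$fold <- folds[cbind(out$condition, out$gene)]
  out
}

#' Simulate a replicated qRT-PCR Ct table
#'
#' Inverts the Livak model: each gene has a per-gene baseline Ct at the
#' control condition, and a true fold change f in a treatment condition
#' lowers its Ct by log2(f); Gaussian noise of `noiseSd` cycles is
#' added per replicate measurement. The reference gene has fold 1
#' everywhere (enforced), so delta-delta-Ct on the noise-free table
#' recovers the configured folds exactly.
#'
#' @param design data.frame `gene`, `condition`, `fold` for the
#'   treatment conditions (default [defaultHeatShockDesign()]).
#' @param referenceGene endogenous-control gene name (fold 1).
#' @param controlCondition control condition label (fold 1).
#' @param baseCt named numeric baseline Ct per gene; unnamed genes get
#'   the `defaultBaseCt`.
#' @param defaultBaseCt baseline for genes absent from `baseCt`.
#' @param noiseSd Gaussian Ct noise sd in cycles (default 0.2).
#' @param replicates biological replicates per gene/condition
#'   (default 3).
#' @param seed integer seed (named stream `"ct_table"`).
#' @return data.frame `gene condition replicate ct`, plus the true
#'   design as attribute `truth`.
#' @export
simulateCtTable <- function(design = defaultHeatShockDesign(),
                            referenceGene = "alaS",
                            controlCondition = "control_30C",
                            baseCt = c(alaS = 16), defaultBaseCt = 21,
                            noiseSd = 0.2, replicates = 3L, seed = 1L) {
  stopifnot(noiseSd >= 0, replicates >= 1L, all(design$fold > 0))
  if (any(design$gene == referenceGene & design$fold != 1))
    stop("the reference gene must have fold 1 in every condition")
  genes <- unique(c(design$gene, referenceGene))
  conditions <- unique(c(controlCondition, design$condition))
  base <- stats::setNames(rep(defaultBaseCt, length(genes)), genes)
  base[names(baseCt)] <- baseCt
  foldOf <- function(g, cond) {
    if (cond == controlCondition || g == referenceGene) return(1)
    i <- which(design$gene == g & design$condition == cond)
    if (length(i) == 0L) 1 else design$fold[i[1L]]
  }
  grid <- expand.grid(gene = genes, condition = conditions,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  withStream(seed, "ct_table", {
    grid$ct <- mapply(function(g, cond) base[[g]] -
                        log2(foldOf(g, cond)), grid$gene, grid$condition) +
      stats::rnorm(nrow(grid), 0, noiseSd)
    grid <- grid[order(grid$gene, grid$condition, grid$replicate), ]
    rownames(grid) <- NULL
    attr(grid, "truth") <- design
    grid
  })
}
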