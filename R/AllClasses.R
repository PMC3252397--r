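#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Positional weight matrix for a fixed-width DNA motif
#'
#' Holds the raw per-position base counts of an aligned site collection
#' together with pseudocount-smoothed probabilities and the background
#' base composition used for log-odds scoring. Probabilities are
#' \eqn{p_{l,b} = (n_{l,b} + c) / (N + 4c)} where \eqn{c} is the
#' pseudocount and \eqn{N} the number of training sites.
#'
#' @slot probs 4 x width numeric matrix of per-position base
#'   probabilities (rows A, C, G, T); every column sums to 1.
#' @slot counts 4 x width numeric matrix of raw base counts.
#' @slot pseudocount non-negative smoothing constant added per base.
#' @slot background length-4 named numeric vector of background base
#'   probabilities summing to 1.
#'
#' @seealso [buildPWM()], [informationContent()], [siteInformation()]
#' @export
setClass("PositionWeightMatrix",
  representation(
    probs = "matrix",
    counts = "matrix",
    pseudocount = "numeric",
    background = "numeric"
  )
)

setValidity("PositionWeightMatrix", function(object) {
  msg <- character()
  if (!identical(rownames(object@probs), DNA_BASES))
    msg <- c(msg, "probs rows must be A, C, G, T")
  if (!identical(dim(object@probs), dim(object@counts)))
    msg <- c(msg, "probs and counts dimensions differ")
  if (any(object@probs < 0))
    msg <- c(msg, "negative probabilities")
  if (any(abs(colSums(object@probs) - 1) > 1e-9))
    msg <- c(msg, "probability columns must sum to 1")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be a single non-negative number")
  if (length(object@background) != 4L ||
      !identical(names(object@background), DNA_BASES) ||
      abs(sum(object@background) - 1) > 1e-9 ||
      any(object@background < 0))
    msg <- c(msg, "background must be named A,C,G,T probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

#' Bipartite sigma-32 promoter model
#'
#' A sigma-32 (heat-shock sigma factor) binding site consists of a
#' 6-bp -35 element and an 8-bp -10 element separated by a spacer of
#' variable length. The model pairs one [PositionWeightMatrix-class]
#' per element with the admissible spacer-length range; scanning
#' enumerates every placement of both blocks with a spacer inside that
#' range and scores it as the sum of the two block log-odds scores.
#'
#' @slot pwm35 width-6 [PositionWeightMatrix-class] for the -35 element.
#' @slot pwm10 width-8 [PositionWeightMatrix-class] for the -10 element.
#' @slot spacerMin,spacerMax integer bounds (inclusive) on the spacer
#'   length in bases.
#'
#' @seealso [fitSigma32Model()], [scanUpstream()]
#' @export
setClass("SigmaPromoterModel",
  representation(
    pwm35 = "PositionWeightMatrix",
    pwm10 = "PositionWeightMatrix",
    spacerMin = "integer",
    spacerMax = "integer"
  )
)

setValidity("SigmaPromoterModel", function(object) {
  msg <- character()
  if (ncol(object@pwm35@probs) != 6L)
    msg <- c(msg, "-35 matrix must have width 6")
  if (ncol(object@pwm10@probs) != 8L)
    msg <- c(msg, "-10 matrix must have width 8")
  if (object@spacerMin < 0L || object@spacerMin > object@spacerMax)
    msg <- c(msg, "need 0 <= spacerMin <= spacerMax")
  if (length(msg)) msg else TRUE
})

#' @describeIn PositionWeightMatrix motif width in bases.
#' @param x,object a `PositionWeightMatrix`.
#' @export
pwmWidth <- function(x) ncol(x@probs)

#' @describeIn PositionWeightMatrix probability matrix accessor.
#' @export
pwmProbs <- function(x) x@probs

#' @describeIn PositionWeightMatrix raw count matrix accessor.
#' @export
pwmCounts <- function(x) x@counts

#' @describeIn PositionWeightMatrix background composition accessor.
#' @export
pwmBackground <- function(x) x@background

#' @describeIn PositionWeightMatrix majority-base consensus string
#'   (ties resolved in A<C<G<T order).
#' @export
consensusSequence <- function(x) {
  paste(DNA_BASES[apply(x@probs, 2L, which.max)], collapse = "")
}

#' @export
setMethod("show", "PositionWeightMatrix", function(object) {
  cat(sprintf(
    "PositionWeightMatrix: width %d, consensus %s\n  pseudocount %.3g, Rsequence %.3f bits\n",
    pwmWidth(object), consensusSequence(object), object@pseudocount,
    informationContent(object)
  ))
})

#' @describeIn SigmaPromoterModel accessor for the -35 element matrix.
#' @export
pwm35 <- function(x) x@pwm35

#' @describeIn SigmaPromoterModel accessor for the -10 element matrix.
#' @export
pwm10 <- function(x) x@pwm10

#' @describeIn SigmaPromoterModel inclusive `c(min, max)` spacer range.
#' @export
spacerRange <- function(x) c(x@spacerMin, x@spacerMax)

#' @export
setMethod("show", "SigmaPromoterModel", function(object) {
  cat(sprintf(
    "SigmaPromoterModel: -35 %s | spacer %d-%d | -10 %s\n  total Rsequence %.3f bits\n",
    consensusSequence(object@pwm35), object@spacerMin, object@spacerMax,
    consensusSequence(object@pwm10),
    informationContent(object@pwm35) + informationContent(object@pwm10)
  ))
})
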