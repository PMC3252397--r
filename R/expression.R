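#' Read a qRT-PCR threshold-cycle table
#'
#' TSV or CSV (by file extension) with header
#' `gene condition replicate ct`; an optional `technical` column marks
#' technical replicates nested inside each biological replicate.
#'
#' @param path path to the table.
#' @return data.frame of Ct measurements.
#' @export
readCtTable <- function(path) {
  tab <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE)
  else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns: ", paste(need, collapse = " "))
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0))
    stop("Ct values must be positive numbers")
  key <- tab[intersect(c("gene", "condition", "replicate", "technical"),
                       names(tab))]
  if (anyDuplicated(key))
    stop("duplicate (gene, condition, replicate) measurements")
  tab
}

#' Mean, standard deviation and count of replicate Ct values
#'
#' @param ct numeric vector of replicate Ct values.
#' @return list with `mean`, `sd` (sample sd, `NA` for n = 1) and `n`.
#' @export
summarizeCt <- function(ct) {
  if (length(ct) == 0L) stop("no Ct measurements")
  list(mean = mean(ct), sd = stats::sd(ct), n = length(ct))
}

.collapseTechnical <- function(ct, replicateModel) {
  if (replicateModel == "biological" && "technical" %in% names(ct)) {
    ct <- stats::aggregate(ct ~ gene + condition + replicate, data = ct,
                           FUN = mean)
  } else if (replicateModel == "pooled" && "technical" %in% names(ct)) {
    ct$replicate <- paste(ct$replicate, ct$technical, sep = ".")
    ct$technical <- NULL
  }
  ct
}

.dctByReplicate <- function(ct, target, reference, condition) {
  t_rows <- ct[ct$gene == target & ct$condition == condition, ]
  r_rows <- ct[ct$gene == reference & ct$condition == condition, ]
  if (nrow(t_rows) == 0L)
    stop("no measurements for gene '", target, "' in condition '",
         condition, "'")
  if (nrow(r_rows) == 0L)
    stop("no measurements for reference '", reference, "' in condition '",
         condition, "'")
  m <- merge(t_rows[c("replicate", "ct")], r_rows[c("replicate", "ct")],
             by = "replicate", suffixes = c("_target", "_reference"))
  if (nrow(m) == 0L)
    stop("no shared replicates between target and reference in '",
         condition, "'")
  m$ct_target - m$ct_reference
}

#' Relative expression by the comparative (delta-delta-Ct) method
#'
#' Livak & Schmittgen quantification: per replicate,
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} normalises the target
#' to an endogenous control measured in the same sample;
#' \eqn{\Delta\Delta Ct} contrasts the mean \eqn{\Delta Ct} of the
#' treatment condition with the control condition, and the fold change
#' is \eqn{2^{-\Delta\Delta Ct}} (amplification efficiency assumed 2).
#' The p-value is a two-sided two-sample Student's t-test comparing the
#' replicate \eqn{\Delta Ct} sets between conditions (equal-variance by
#' default, Welch via `varEqual = FALSE`); with fewer than 2 replicates
#' in either condition it is `NA` and the result is flagged
#' non-significant.
#'
#' @param ct Ct table as from [readCtTable()].
#' @param target gene to quantify.
#' @param reference endogenous-control gene (e.g. `alaS`).
#' @param controlCondition,treatCondition condition labels.
#' @param alpha significance level on the t-test (strict `<`).
#' @param fcFloor minimal fold change called significant (default 2).
#' @param varEqual equal-variance t-test (default) or Welch.
#' @param replicateModel `"biological"` averages technical replicates
#'   within each biological replicate first; `"pooled"` treats every
#'   (replicate, technical) pair as an independent unit.
#' @return one-row data.frame: `gene`, `condition`, `mean_dct_treat`,
#'   `mean_dct_control`, `ddct`, `fold_change`, `p_value`,
#'   `significant`.
#' @export
relativeExpression <- function(ct, target, reference,
                               controlCondition, treatCondition,
                               alpha = 0.05, fcFloor = 2.0,
                               varEqual = TRUE,
                               replicateModel = c("biological", "pooled")) {
  replicateModel <- match.arg(replicateModel)
  ct <- .collapseTechnical(ct, replicateModel)
  dct_c <- .dctByReplicate(ct, target, reference, controlCondition)
  dct_t <- .dctByReplicate(ct, target, reference, treatCondition)
  ddct <- mean(dct_t) - mean(dct_c)
  fold <- 2^(-ddct)
  p <- if (length(dct_c) >= 2L && length(dct_t) >= 2L &&
           (stats::sd(dct_c) > 0 || stats::sd(dct_t) > 0)) {
    stats::t.test(dct_t, dct_c, var.equal = varEqual)$p.value
  } else NA_real_
  res <- data.frame(
    gene = target, condition = treatCondition,
    mean_dct_treat = mean(dct_t), mean_dct_control = mean(dct_c),
    ddct = ddct, fold_change = fold, p_value = p,
    significant = FALSE
  )
  res$significant <- callSignificance(res, alpha, fcFloor)
  res
}

#' Significance rule for relative-expression results
#'
#' A gene/condition is called significantly up-regulated when the
#' t-test p-value is strictly below `alpha` AND the fold change is at
#' least `fcFloor`. An undefined p-value never passes.
#'
#' @param result data.frame with `p_value` and `fold_change` columns.
#' @param alpha significance level (default 0.05).
#' @param fcFloor fold-change floor (default 2).
#' @return logical vector.
#' @export
callSignificance <- function(result, alpha = 0.05, fcFloor = 2.0) {
  !is.na(result$p_value) & result$p_value < alpha &
    result$fold_change >= fcFloor
}

#' Relative expression for every target gene and treatment condition
#'
#' @inheritParams relativeExpression
#' @param targets genes to quantify; default every gene except the
#'   reference.
#' @param treatConditions default every condition except the control.
#' @return data.frame with one row per (gene, condition).
#' @export
relativeExpressionTable <- function(ct, reference, controlCondition,
                                    targets = NULL, treatConditions = NULL,
                                    alpha = 0.05, fcFloor = 2.0,
                                    varEqual = TRUE,
                                    replicateModel = c("biological",
                                                       "pooled")) {
  replicateModel <- match.arg(replicateModel)
  if (is.null(targets))
    targets <- setdiff(unique(ct$gene), reference)
  if (is.null(treatConditions))
    treatConditions <- setdiff(unique(ct$condition), controlCondition)
  rows <- lapply(treatConditions, function(cond)
    do.call(rbind, lapply(targets, function(g)
      relativeExpression(ct, g, reference, controlCondition, cond,
                         alpha, fcFloor, varEqual, replicateModel))))
  do.call(rbind, rows)
}

#' Fold-change ratio between two genes in the same condition
#'
#' @param a,b one-row results from [relativeExpression()].
#' @return `a$fold_change / b$fold_change`.
#' @export
betweenGeneRatio <- function(a, b) {
  if (!identical(a$condition, b$condition))
    stop("results are from different conditions: '", a$condition,
         "' vs '", b$condition, "'")
  a$fold_change / b$fold_change
}
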