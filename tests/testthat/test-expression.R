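.ctRow <- function(gene, condition, replicate, ct)
  data.frame(gene = gene, condition = condition, replicate = replicate,
             ct = ct)

# small hand-built table: target 1 cycle lower under treatment
.toyCt <- function(shift_treat = -1, noise = c(0, 0, 0)) {
  rbind(
    .ctRow("tgt", "ctrl", 1:3, 20 + noise),
    .ctRow("tgt", "heat", 1:3, 20 + shift_treat + noise),
    .ctRow("ref", "ctrl", 1:3, 16),
    .ctRow("ref", "heat", 1:3, 16)
  )
}

test_that("replicate Ct summaries match a two-pass oracle", {
  expect_equal(summarizeCt(c(21, 21, 21)), list(mean = 21, sd = 0, n = 3L))
  expect_equal(summarizeCt(c(20, 21, 22)), list(mean = 21, sd = 1, n = 3L))
  expect_error(summarizeCt(numeric(0)), "no Ct")
  set.seed(19)
  x <- rnorm(7, 25, 2)
  s <- summarizeCt(x)
  m <- sum(x) / length(x)
  expect_equal(s$mean, m, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(sum((x - m)^2) / (length(x) - 1)),
               tolerance = 1e-12)
})

test_that("delta-delta-Ct recovers fold changes from Ct differences", {
  r0 <- relativeExpression(.toyCt(0), "tgt", "ref", "ctrl", "heat")
  expect_equal(r0$ddct, 0)
  expect_equal(r0$fold_change, 1)
  r1 <- relativeExpression(.toyCt(-1), "tgt", "ref", "ctrl", "heat")
  expect_equal(r1$fold_change, 2)
  r3 <- relativeExpression(.toyCt(-3), "tgt", "ref", "ctrl", "heat")
  expect_equal(r3$fold_change, 8)
  expect_error(relativeExpression(.toyCt(), "absent", "ref", "ctrl", "heat"),
               "absent")
})

test_that("the generator's configured folds are recovered exactly at zero noise", {
  design <- data.frame(gene = c("g1", "g2", "g3"), condition = "hs",
                       fold = c(8, 23, 1.15))
  ct <- simulateCtTable(design, referenceGene = "alaS",
                        controlCondition = "ctrl", noiseSd = 0, seed = 5)
  for (i in seq_len(nrow(design))) {
    r <- relativeExpression(ct, design$gene[i], "alaS", "ctrl", "hs")
    expect_equal(r$fold_change, design$fold[i], tolerance = 1e-9)
  }
  # between-gene ratios at zero noise
  r1 <- relativeExpression(ct, "g2", "alaS", "ctrl", "hs")
  r2 <- relativeExpression(ct, "g1", "alaS", "ctrl", "hs")
  expect_equal(betweenGeneRatio(r1, r2), 23 / 8, tolerance = 1e-9)
})

test_that("a constant plate shift cancels through the reference gene", {
  set.seed(23)
  base <- .toyCt(-2, noise = rnorm(3, 0, 0.2))
  shifted <- base
  shifted$ct[shifted$condition == "heat"] <-
    shifted$ct[shifted$condition == "heat"] + 3.7
  a <- relativeExpression(base, "tgt", "ref", "ctrl", "heat")
  b <- relativeExpression(shifted, "tgt", "ref", "ctrl", "heat")
  expect_equal(a$ddct, b$ddct, tolerance = 1e-12)
  expect_equal(a$fold_change, b$fold_change, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("significance needs both p below alpha and fold at the floor", {
  mk <- function(p, fc) data.frame(p_value = p, fold_change = fc)
  expect_true(callSignificance(mk(0.01, 3.0)))
  expect_false(callSignificance(mk(0.01, 1.5)))
  expect_false(callSignificance(mk(0.20, 5.0)))
  expect_false(callSignificance(mk(NA_real_, 5.0)))
  expect_true(callSignificance(mk(0.049, 2.0)))
  expect_false(callSignificance(mk(0.05, 3.0)))  # strict inequality
})

test_that("between-gene ratios are condition-guarded arithmetic", {
  a <- data.frame(condition = "hs", fold_change = 40)
  b <- data.frame(condition = "hs", fold_change = 2)
  expect_equal(betweenGeneRatio(a, b), 20)
  expect_equal(betweenGeneRatio(a, a), 1)
  b$condition <- "ctrl"
  expect_error(betweenGeneRatio(a, b), "different conditions")
})

test_that("reciprocal contrasts have reciprocal folds", {
  set.seed(29)
  ct <- .toyCt(-2, noise = rnorm(3, 0, 0.3))
  fwd <- relativeExpression(ct, "tgt", "ref", "ctrl", "heat")
  rev <- relativeExpression(ct, "tgt", "ref", "heat", "ctrl")
  expect_equal(fwd$fold_change * rev$fold_change, 1, tolerance = 1e-12)
})

test_that("technical replicates collapse before biological-replicate testing", {
  tech <- expand.grid(gene = c("tgt", "ref"), condition = c("ctrl", "heat"),
                      replicate = 1:3, technical = 1:3,
                      stringsAsFactors = FALSE)
  tech$ct <- 20 - (tech$gene == "tgt" & tech$condition == "heat") * 2 +
    0.05 * tech$technical
  bio <- relativeExpression(tech, "tgt", "ref", "ctrl", "heat",
                            replicateModel = "biological")
  pooled <- relativeExpression(tech, "tgt", "ref", "ctrl", "heat",
                               replicateModel = "pooled")
  expect_equal(bio$fold_change, 4, tolerance = 1e-9)
  expect_equal(pooled$fold_change, 4, tolerance = 1e-9)
})

test_that("full expression tables carry one row per gene and condition", {
  ct <- simulateCtTable(noiseSd = 0, seed = 3)
  tab <- relativeExpressionTable(ct, "alaS", "control_30C")
  expect_identical(nrow(tab), 9L)
  expect_setequal(unique(tab$gene), c("Afe_1009", "Afe_1437", "Afe_2172"))
  truth <- attr(ct, "truth")
  for (i in seq_len(nrow(truth))) {
    got <- tab$fold_change[tab$gene == truth$gene[i] &
                             tab$condition == truth$condition[i]]
    expect_equal(got, truth$fold[i], tolerance = 1e-9)
  }
})
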