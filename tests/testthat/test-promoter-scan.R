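test_that("PWM construction matches hand-counted frequencies", {
  p <- buildPWM(c("ACG", "ACT", "ACG"), pseudocount = 0)
  expect_equal(pwmProbs(p)[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pwmProbs(p)[, 2], c(A = 0, C = 1, G = 0, T = 0))
  expect_equal(pwmProbs(p)[, 3], c(A = 0, C = 0, G = 2 / 3, T = 1 / 3))
  expect_equal(pwmCounts(p)[, 3], c(A = 0, C = 0, G = 2, T = 1))

  onehot <- buildPWM(rep("TTGAAA", 18), pseudocount = 0)
  expect_equal(pwmWidth(onehot), 6L)
  expect_true(all(pwmProbs(onehot)[cbind(
    match(strsplit("TTGAAA", "")[[1]], c("A", "C", "G", "T")), 1:6)] == 1))

  set.seed(5)
  sites <- replicate(18, randomDNA(6))
  sm <- buildPWM(sites, pseudocount = 0.5)
  expect_equal(unname(colSums(pwmProbs(sm))), rep(1, 6), tolerance = 1e-12)
  expect_identical(consensusSequence(buildPWM("ACGT", pseudocount = 1,
                                              background = uniformBackground())),
                   "ACGT")

  expect_error(buildPWM(c("ACG", "ACGT")), "unequal")
  expect_error(buildPWM(character(0)), "empty")
})

test_that("information content: uniform 0, one-hot 2 bits/position, entropy case", {
  onehot <- buildPWM(rep("TTGAAA", 18), pseudocount = 0)
  expect_equal(informationContent(onehot), 12)
  set.seed(2)
  uniform <- buildPWM(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 0)
  expect_equal(informationContent(uniform), 0)
  p <- buildPWM(c("ACG", "ACT", "ACG"), pseudocount = 0)
  expect_equal(informationContent(p), 5.0817, tolerance = 1e-4)
  for (i in 1:10) {
    pwm <- buildPWM(replicate(18, randomDNA(6)), pseudocount = 0.5)
    ic <- informationContent(pwm)
    expect_gte(ic, 0)
    expect_lte(ic, 12)
  }
})

test_that("individual information evaluates the log-odds formula directly", {
  onehot <- buildPWM(rep("TTGAAA", 18), pseudocount = 0)
  expect_equal(siteInformation(onehot, "TTGAAA"), 12)
  # a column with probability 0.5 contributes exactly 1 bit
  half <- buildPWM(c(rep("A", 9), rep("C", 9)), pseudocount = 0)
  expect_equal(siteInformation(half, "A"), 1)
  # a base unseen among 18 sites under pseudocount 0.5: 2 + log2(0.025)
  unseen <- buildPWM(rep("G", 18), pseudocount = 0.5)
  expect_equal(siteInformation(unseen, "T"), 2 + log2(0.025),
               tolerance = 1e-9)
  expect_equal(2 + log2(0.025), -3.3219, tolerance = 1e-4)
  expect_error(siteInformation(onehot, "TTGA"), "width")
})

test_that("the consensus site maximises individual information", {
  set.seed(9)
  for (i in 1:20) {
    pwm <- buildPWM(replicate(18, randomDNA(8)), pseudocount = 0.5)
    consensus <- consensusSequence(pwm)
    ri_max <- siteInformation(pwm, consensus)
    for (j in 1:20)
      expect_lte(siteInformation(pwm, randomDNA(8)), ri_max + 1e-12)
  }
})

test_that("background rescoring shifts all site scores uniformly", {
  set.seed(4)
  pwm <- buildPWM(replicate(18, randomDNA(6)), pseudocount = 0.5)
  halfbg <- uniformBackground() / 2   # +1 bit per position for any site
  for (i in 1:10) {
    s <- randomDNA(6)
    expect_equal(siteInformation(pwm, s, background = halfbg),
                 siteInformation(pwm, s) + 6, tolerance = 1e-12)
  }
})

test_that("model fitting takes the spacer range from the training set", {
  ts <- data.frame(site35 = rep("CTTGAA", 3), spacer_len = c(13, 13, 13),
                   site10 = rep("CCCCATAT", 3))
  m <- fitSigma32Model(ts)
  expect_identical(spacerRange(m), c(13L, 13L))
  ts$spacer_len <- c(11, 13, 15)
  expect_identical(spacerRange(fitSigma32Model(ts)), c(11L, 15L))
  m2 <- fitSigma32Model(simulateTrainingSet(seed = 42))
  expect_identical(pwmWidth(pwm35(m2)), 6L)
  expect_identical(pwmWidth(pwm10(m2)), 8L)
  expect_equal(unname(colSums(pwmProbs(pwm10(m2)))), rep(1, 8),
               tolerance = 1e-12)
  expect_error(fitSigma32Model(ts[0, ]), "at least 2")
})

test_that("scanning equals brute-force enumeration on small windows", {
  set.seed(13)
  for (i in 1:100) {
    ts <- simulateTrainingSet(n = 6, mutationRate = 0.3,
                              spacerRange = c(2L, 4L), seed = i)
    model <- fitSigma32Model(ts)
    window <- randomDNA(sample(20:60, 1))
    got <- as.data.frame(scanUpstream(model, window))
    want <- oracleScan(model, window)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$pos35, want$pos35)
    expect_identical(got$spacer_len, want$spacer_len)
    expect_equal(got$total_score, want$total_score, tolerance = 1e-9)
    expect_identical(got$dist_to_start, want$dist_to_start)
  }
})

test_that("a planted consensus pair tops the hit list", {
  ts <- simulateTrainingSet(seed = 42)
  model <- fitSigma32Model(ts)
  set.seed(3)
  window <- randomDNA(200)
  substr(window, 120, 125) <- "CTTGAA"
  substr(window, 139, 146) <- "CCCCATAT"   # spacer 13
  hits <- scanUpstream(model, window)
  expect_identical(hits$pos35[1], 120L)
  expect_identical(hits$spacer_len[1], 13L)
  expect_identical(hits$pos10[1], 139L)
  expect_equal(hits$total_score[1], hits$bits35[1] + hits$bits10[1])
  # invariant links between reported columns
  expect_true(all(hits$pos10 == hits$pos35 + 6L + hits$spacer_len))
  expect_true(all(diff(hits$total_score) <= 1e-12))
})

test_that("windows below the minimal footprint are rejected", {
  model <- fitSigma32Model(simulateTrainingSet(seed = 1,
                                               spacerRange = c(2L, 4L)))
  expect_error(scanUpstream(model, randomDNA(13)), "footprint")
  expect_silent(scanUpstream(model, randomDNA(16)))
})

test_that("promoter report recovers planted positions for a gene trio", {
  ts <- simulateTrainingSet(seed = 11)
  model <- fitSigma32Model(ts)
  wins <- list()
  truth <- list()
  for (i in 1:3) {
    u <- simulateUpstream(planted = TRUE, seed = 11L + i)
    wins[[paste0("gene", i)]] <- u$seq
    truth[[paste0("gene", i)]] <- u$truth
  }
  rep <- reportPromoters(model, unlist(wins), topK = 1)
  expect_identical(nrow(rep), 3L)
  for (i in 1:3) {
    row <- rep[rep$locus == paste0("gene", i), ]
    expect_identical(row$pos35, truth[[i]]$pos35)
    expect_identical(row$spacer_len, truth[[i]]$spacer_len)
    expect_identical(row$offset_from_ATG, row$pos35 - 201L)
    expect_lt(row$offset_from_ATG, 0L)
  }
  rep3 <- reportPromoters(model, unlist(wins), topK = 5)
  expect_identical(nrow(rep3), 15L)
})
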