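test_that("activation capture exposes every input and hidden neuron per instance", {
  ts <- makeTrainingSet(n = 50, noise = 0, seed = 14)
  m <- fitModel(classifierSpec("deep", "binary",
                               params = list(epochs = 80), seed = 1),
                ts$x, ts$y)
  act <- activations(m, ts$x)
  expect_equal(dim(act$input), dim(ts$x))
  expect_equal(vapply(act$hidden, ncol, 0L), c(8L, 32L, 16L, 8L))
  expect_true(all(vapply(act$hidden, nrow, 0L) == nrow(ts$x)))
  expect_true(all(unlist(act$hidden) >= 0))   # post-ReLU
  shallow <- fitModel(classifierSpec("naive_bayes", "binary"), ts$x, ts$y)
  expect_error(activations(shallow, ts$x), "deep")
  expect_error(binarizeActivations(shallow, ts$x, ts$y), "deep")
})

test_that("a dead hidden neuron yields an all-zero column in both tables", {
  # fixed weights: hidden unit 2 has a large negative bias, so it never fires
  W1 <- matrix(0, 4, 2); W1[1, 1] <- 1; W1[1, 2] <- 1
  m <- makeFixedMlp(W1, b1 = c(0, -100), w2 = c(1, 1), b2 = 0)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  tab <- binarizeActivations(m, x, labels = rep(c(TRUE, FALSE), 5),
                             includeInput = FALSE)
  dead <- which(tab@neurons$unit == 2 & tab@neurons$layer == "h1")
  expect_true(all(tab@xPlus[, dead] == 0))
  expect_true(all(tab@xMinus[, dead] == 0))
})

test_that("the information-gain scan recovers the planted threshold", {
  cfg <- syntheticConfig(nPsychosis = 200, nHc = 20, labelNoise = 0,
                         protocolShift = 0, seed = 23)
  co <- generateCohort(cfg)
  pat <- colData(co)$group == "psychosis"
  x <- t(assay(co, "betas")[c("L_DLPFC", "R_DLPFC", "L_SPC", "R_SPC"), pat])
  y <- as.logical(groundTruth(co)$label)
  ig <- infoGainThresholds(x, y, topK = 1)
  top <- ig[which.max(ig$gain), ]
  expect_equal(top$feature, "L_DLPFC")
  # within one scan step of the planted threshold
  v <- sort(x[, "L_DLPFC"])
  step <- max(diff(v[findInterval(top$threshold, v) + c(0, 1)]), 1e-6)
  expect_lte(abs(top$threshold - 0.017), step)
})

test_that("label permutation under a fixed binarization spec only reroutes rows", {
  ts <- makeTrainingSet(n = 40, noise = 0.1, seed = 31)
  m <- fitModel(classifierSpec("deep", "binary",
                               params = list(epochs = 60), seed = 2),
                ts$x, ts$y)
  tab <- binarizeActivations(m, ts$x, ts$y)
  yPerm <- withr::with_seed(5, sample(ts$y))
  tab2 <- binarizeActivations(m, ts$x, yPerm, neurons = tab@neurons)
  expect_identical(tab@neurons$id, tab2@neurons$id)
  all1 <- rbind(tab@xPlus, tab@xMinus)
  all2 <- rbind(tab2@xPlus, tab2@xMinus)
  expect_identical(all1[order(rownames(all1)), ], all2[order(rownames(all2)), ])
  expect_equal(nrow(tab2@xPlus), sum(yPerm))
})

test_that("an empty cover yields an empty rule set with zero coverage", {
  ts <- makeTrainingSet(n = 40, noise = 0, seed = 3)
  m <- fitModel(classifierSpec("deep", "binary",
                               params = list(epochs = 60), seed = 2),
                ts$x, ts$y)
  tab <- binarizeActivations(m, ts$x, ts$y)
  rs <- extractRules(list(aPlus = integer(0), aMinus = integer(0)),
                     tab, m, ts$x, ts$y)
  expect_length(rules(rs), 0)
  expect_equal(ruleCoverage(rs), 0)
})

test_that("rule extraction on noise-free planted data reaches full fidelity", {
  ts <- makeTrainingSet(n = 150, noise = 0, seed = 41)
  m <- fitModel(classifierSpec("deep", "binary",
                               params = list(epochs = 200), seed = 7),
                ts$x, ts$y)
  expect_equal(mean(predictModel(m, ts$x) == ts$y), 1)
  tab <- binarizeActivations(m, ts$x, ts$y)
  sol <- solveSetCover(tab)
  rs <- extractRules(sol, tab, m, ts$x, ts$y)
  top <- rules(rs)[[1]]
  expect_equal(top$literals[[1]]$feature, "L_DLPFC")
  expect_equal(top$class, "Improver")
  expect_equal(fidelity(rs), 1)
  # ranked-prefix fidelity is monotone non-decreasing by construction
  deepPred <- predictModel(m, ts$x)
  fids <- vapply(seq_along(rules(rs)), function(k)
    mean(xaiPrognosis:::.rulesPredict(rules(rs)[seq_len(k)],
                                      rs@defaultClass, ts$x) == deepPred), 0)
  expect_true(all(diff(fids) >= -1e-12))
})

test_that("the context report situates thresholds between group means", {
  rs <- new("RuleSet",
            rules = list(list(class = "Improver",
                              literals = list(list(feature = "L_DLPFC",
                                                   op = ">",
                                                   threshold = 0.017)),
                              accuracy = 1, agreement = 1)),
            aPlus = 1L, aMinus = integer(0), fidelity = 1, coverage = 1,
            defaultClass = "non-Improver")
  cfg <- syntheticConfig(nPsychosis = 20000L, nHc = 20000L, protocolShift = 0,
                         seed = 77)
  co <- generateCohort(cfg)
  keep <- c("L_DLPFC", "R_DLPFC", "L_SPC", "R_SPC")
  hc <- t(assay(co, "betas")[keep, colData(co)$group == "HC"])
  pt <- t(assay(co, "betas")[keep, colData(co)$group == "psychosis"])
  rep1 <- ruleContextReport(rs, hc, pt)
  expect_true(rep1$intermediate)
  expect_lt(abs(rep1$hcMean - 0.15), 0.02)
  expect_lt(abs(rep1$patientMean - (-0.13)), 0.02)
  # threshold above both means is not intermediate
  rs2 <- rs; rs2@rules[[1]]$literals[[1]]$threshold <- 2
  expect_false(ruleContextReport(rs2, hc, pt)$intermediate)
  expect_error(ruleContextReport(rs, hc[, 3:4], pt), "absent")
})
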