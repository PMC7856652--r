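learnersBinary <- c("logistic", "naive_bayes", "svm_poly", "kstar",
                    "adaboost", "j48", "random_forest", "deep")

test_that("every learner is deterministic given seed and data", {
  ts <- makeTrainingSet(n = 60, noise = 0.1, seed = 3)
  probe <- ts$x[1:15, ]
  for (nm in learnersBinary) {
    p <- if (nm == "deep") list(epochs = 60) else list()
    m1 <- fitModel(classifierSpec(nm, "binary", params = p, seed = 11),
                   ts$x, ts$y)
    m2 <- fitModel(classifierSpec(nm, "binary", params = p, seed = 11),
                   ts$x, ts$y)
    expect_identical(predictModel(m1, probe), predictModel(m2, probe),
                     info = nm)
  }
})

test_that("the deep model fits separable planted-rule data to 100% within 200 epochs", {
  ts <- makeTrainingSet(n = 120, noise = 0, seed = 5)
  m <- fitModel(classifierSpec("deep", "binary",
                               params = list(epochs = 200), seed = 2),
                ts$x, ts$y)
  expect_equal(mean(predictModel(m, ts$x) == ts$y), 1)
  out <- deepOutput(m, ts$x)
  expect_true(all(out >= 0 & out <= 1))  # sigmoid range
})

test_that("naive Bayes falls back on the prior when likelihoods are uninformative", {
  # identical class-conditional feature distributions; prior 2:1 Improver
  x <- matrix(rep(c(1, 2, 3, 1.5, 2.5, 3.5), 3), ncol = 1,
              dimnames = list(NULL, "L_DLPFC"))
  y <- rep(c(TRUE, TRUE, FALSE), each = 6)
  m <- fitModel(classifierSpec("naive_bayes", "binary"), x, y)
  expect_true(all(predictModel(m, x)))
})

test_that("degenerate or malformed training inputs are rejected", {
  ts <- makeTrainingSet(n = 30, noise = 0, seed = 1)
  expect_error(fitModel(classifierSpec("j48", "binary"), ts$x,
                        rep(TRUE, nrow(ts$x))), "single outcome class")
  xBad <- ts$x; xBad[1, 1] <- NA
  expect_error(fitModel(classifierSpec("logistic", "binary"), xBad, ts$y),
               "non-finite")
  m <- fitModel(classifierSpec("logistic", "binary"), ts$x, ts$y)
  expect_error(predictModel(m, ts$x[, c(2, 1, 3, 4)]), "layout mismatch")
  expect_error(classifierSpec("perceptron", "binary"), "unknown")
})

test_that("K* self-similarity is minimal and the similarity is a log-probability", {
  withr::with_seed(8, {
    train <- matrix(rnorm(40), ncol = 2,
                    dimnames = list(NULL, c("a", "b")))
    x <- train[7, ]
    sSelf <- kstarSimilarity(x, x, train, blend = 0.2)
    expect_gte(sSelf, 0)
    for (i in sample(nrow(train), 8))
      expect_lte(sSelf, kstarSimilarity(x, train[i, ], train, blend = 0.2) + 1e-12)
  })
  expect_error(kstarSimilarity(1, 1, matrix(1:3, ncol = 1), blend = 0),
               "degenerate")
})

test_that("K* classification matches exhaustive transformation-probability computation", {
  # 3 stored instances in 1-D; oracle recomputes the blend sphere and the
  # normalized transformation probabilities from their definitions
  train <- matrix(c(0, 1, 5), ncol = 1, dimnames = list(NULL, "f1"))
  y <- c(TRUE, TRUE, FALSE)
  blend <- 0.2
  oracleVote <- function(a) {
    d <- abs(train[, 1] - a)
    dd <- d - min(d)
    m0 <- sum(dd < 1e-12); N <- length(d)
    target <- m0 + blend * (N - m0)
    x0 <- uniroot(function(s) sum(exp(-dd / s)) - target,
                  lower = 1e-9, upper = 1e6, tol = 1e-12)$root
    q <- exp(-d / x0)
    p <- q / sum(q)
    sum(p[y]) > sum(p[!y])
  }
  m <- fitModel(classifierSpec("kstar", "binary", params = list(blend = blend)),
                train, y)
  probes <- matrix(c(-0.5, 0.6, 2.9, 4.2, 6), ncol = 1,
                   dimnames = list(NULL, "f1"))
  expect_identical(predictModel(m, probes),
                   vapply(probes[, 1], oracleVote, TRUE))
})

test_that("the polynomial exponent search plateaus correctly", {
  # linearly separable: exponent 1 suffices
  ts <- makeTrainingSet(n = 80, noise = 0, seed = 6)
  plan <- splitPlan(nRepetitions = 15, seed = 2)
  e1 <- svmExponentSearch(ts$x, ts$y, exponents = 1:3, plan = plan)
  expect_equal(as.integer(e1), 1L)
  # XOR pattern: a linear kernel cannot beat chance, degree >= 2 can
  withr::with_seed(4, {
    n <- 160
    x <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- (x[, 1] * x[, 2]) > 0
  })
  e2 <- svmExponentSearch(x, y, exponents = 1:3, plateauTol = 0.02,
                          plan = splitPlan(nRepetitions = 15, seed = 3))
  expect_gte(as.integer(e2), 2L)
  acc <- attr(e2, "accuracies")
  expect_gt(acc[2] - acc[1], 0.15)   # direct-fit verification of the XOR gap
  expect_error(svmExponentSearch(x, y, exponents = integer(0)), "empty")
  expect_identical(as.integer(svmExponentSearch(x, y, exponents = 1:3,
                              plateauTol = 0.02,
                              plan = splitPlan(nRepetitions = 15, seed = 3))),
                   as.integer(e2))   # reproducible under fixed seed
})

test_that("equal-width binning follows the documented arithmetic", {
  b <- binContinuousOutcome(c(-20, 20), nBins = 10)
  expect_equal(diff(b$edges)[1], 4)
  expect_equal(assignBins(-20, b$edges), 0L)
  expect_equal(assignBins(19.9, b$edges), 9L)
  expect_equal(assignBins(c(-100, 100), b$edges), c(0L, 9L))  # clamping
  b2 <- binContinuousOutcome(c(-1, 1), nBins = 2)
  expect_equal(b2$labels, c(0L, 1L))
  expect_warning(binContinuousOutcome(rep(3, 5)), "zero range")
})

test_that("midpoint predictions inside the correct bin bound the RMSE by half a bin width", {
  withr::with_seed(2, v <- runif(200, -20, 20))
  b <- binContinuousOutcome(v, nBins = 10)
  pred <- b$mids[b$labels + 1L]       # always the correct bin's midpoint
  rmse <- sqrt(mean((pred - v)^2))
  expect_lte(rmse, diff(b$edges)[1] / 2)
})

test_that("nominal-only learners are binned on the continuous task; regressors are not", {
  ts <- makeTrainingSet(n = 60, noise = 0.1, seed = 9)
  for (nm in c("naive_bayes", "j48", "random_forest")) {
    m <- fitModel(classifierSpec(nm, "continuous"), ts$x, ts$delta)
    pred <- predictModel(m, ts$x)
    expect_true(all(pred %in% m@fit$bins$mids), info = nm)
  }
  mLin <- fitModel(classifierSpec("linear", "continuous"), ts$x, ts$delta)
  predLin <- predictModel(mLin, ts$x)
  expect_true(all(is.finite(predLin)))
  expect_gt(length(unique(predLin)), 10)  # not quantized to bins
})
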