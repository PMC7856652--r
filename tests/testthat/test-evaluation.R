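# small helper: hand-built ledgers for closed-form checks
mkLedger <- function(df, task = "binary") {
  attr(df, "task") <- task
  df
}

test_that("splits partition the cohort with the pinned test size, deterministically", {
  plan <- splitPlan(nRepetitions = 25, seed = 4)
  sp <- makeSplits(82, plan)
  for (s in sp) {
    expect_equal(length(s$test), 8)              # floor(82 * 0.1)
    expect_equal(sort(c(s$train, s$test)), 1:82)  # exact partition
  }
  expect_identical(makeSplits(82, plan), sp)
  expect_false(identical(makeSplits(82, splitPlan(25, seed = 5)), sp))
  expect_error(makeSplits(8, plan), "at least 10")
})

test_that("stratified splits keep every class represented in each test set", {
  y <- rep(c(TRUE, FALSE), c(45, 15))
  plan <- splitPlan(nRepetitions = 30, seed = 1, stratified = TRUE)
  sp <- makeSplits(60, plan, labels = y)
  for (s in sp) {
    expect_true(any(y[s$test]))
    expect_true(any(!y[s$test]))
  }
  yTiny <- rep(c(TRUE, FALSE), c(59, 1))
  expect_error(makeSplits(60, plan, labels = yTiny), "impossible")
  expect_error(makeSplits(60, plan), "one label per subject")
})

test_that("the harness evaluates all classifiers on identical split sequences", {
  ts <- makeTrainingSet(n = 40, noise = 0.1, seed = 8)
  led <- runHarness(list(classifierSpec("majority", "binary"),
                         classifierSpec("naive_bayes", "binary"),
                         classifierSpec("j48", "binary")),
                    ts$x, ts$y, splitPlan(12, seed = 3))
  byRep <- split(led, led$rep)
  for (d in byRep) {
    idSets <- tapply(d$id, d$classifier, function(v) paste(sort(v), collapse = ","))
    expect_equal(length(unique(idSets)), 1L)
  }
})

test_that("an oracle classifier scores 100% on every repetition", {
  # memorizing oracle: K* with the full data is exact on training rows, so
  # instead verify through a constructed ledger
  led <- mkLedger(data.frame(rep = rep(1:5, each = 4),
                             id = rep(letters[1:4], 5),
                             classifier = "oracle",
                             truth = rep(c(TRUE, FALSE), 10),
                             pred = rep(c(TRUE, FALSE), 10)))
  s <- summarizeBinary(led)
  expect_equal(s$accuracy, 1)
  expect_equal(s$accuracyHi - s$accuracyLo, 0)
  expect_equal(s$improverAccuracy, 1)
})

test_that("an always-non-Improver ledger yields 0%/100% class-wise accuracy", {
  led <- mkLedger(data.frame(rep = rep(1:4, each = 5),
                             id = rep(letters[1:5], 4),
                             classifier = "pessimist",
                             truth = rep(c(TRUE, TRUE, FALSE, FALSE, TRUE), 4),
                             pred = FALSE))
  s <- summarizeBinary(led)
  expect_equal(s$improverAccuracy, 0)
  expect_equal(s$nonImproverAccuracy, 1)
  expect_equal(s$accuracy, 0.4)
})

test_that("CI width shrinks as one over the square root of the repetition count", {
  withr::with_seed(11, {
    mk <- function(R) {
      nTest <- 10
      correct <- runif(R * nTest) < 0.7
      mkLedger(data.frame(rep = rep(seq_len(R), each = nTest),
                          id = as.character(rep(1:nTest, R)),
                          classifier = "c", truth = TRUE, pred = correct))
    }
    w <- function(led) { s <- summarizeBinary(led); s$accuracyHi - s$accuracyLo }
    ratio <- w(mk(1600)) / w(mk(100))
    expect_lt(abs(ratio - 0.25), 0.08)
  })
})

test_that("RMSE summaries match closed forms", {
  led1 <- mkLedger(data.frame(rep = 1, id = "a", classifier = "m",
                              truth = 0, pred = 3), task = "continuous")
  expect_equal(summarizeContinuous(led1, deltaFrom = NULL)$rmse, 3)
  withr::with_seed(3, {
    truth <- rnorm(40, sd = 5)
    led2 <- mkLedger(data.frame(rep = rep(1:4, each = 10), id = as.character(1:10),
                                classifier = "meanpred", truth = truth,
                                pred = ave(truth, rep(1:4, each = 10))),
                     task = "continuous")
    perRep <- xaiPrognosis:::.perRepRmse(led2)
    popSd <- vapply(split(truth, rep(1:4, each = 10)),
                    function(v) sqrt(mean((v - mean(v))^2)), 0)
    expect_equal(unname(perRep$rmse[order(perRep$rep)]), unname(popSd),
                 tolerance = 1e-9)
  })
  expect_error(summarizeContinuous(led1, deltaFrom = "deep"), "absent")
})

test_that("perfect predictions give zero RMSE", {
  led <- mkLedger(data.frame(rep = rep(1:3, each = 2), id = c("a", "b"),
                             classifier = "exact", truth = c(1.5, -2),
                             pred = c(1.5, -2)), task = "continuous")
  expect_equal(summarizeContinuous(led, deltaFrom = NULL)$rmse, 0)
})

test_that("pooling averages per repetition and excludes the deep learner", {
  base <- data.frame(rep = rep(1:6, each = 5), id = as.character(1:5),
                     truth = TRUE)
  mk <- function(nm, acc) {
    d <- base; d$classifier <- nm
    d$pred <- rep(c(rep(TRUE, acc * 5), rep(FALSE, 5 - acc * 5)), 6)
    d
  }
  led <- mkLedger(rbind(mk("naive_bayes", 0.6), mk("j48", 0.8),
                        mk("deep", 0.2)))
  pooled <- poolShallow(led, methods = c("naive_bayes", "j48"))
  expect_equal(pooled$accuracy, 0.7)        # deep's 0.2 plays no part
  expect_equal(pooled$classifier, "pooled")
  expect_error(poolShallow(led, methods = "j48"), "at least two")
})

test_that("pooled CI is no wider than the widest member CI", {
  ts <- makeTrainingSet(n = 40, noise = 0.15, seed = 12)
  led <- runHarness(list(classifierSpec("naive_bayes", "binary"),
                         classifierSpec("j48", "binary"),
                         classifierSpec("kstar", "binary")),
                    ts$x, ts$y, splitPlan(40, seed = 6))
  s <- summarizeBinary(led)
  widths <- s$accuracyHi - s$accuracyLo
  p <- poolShallow(led, methods = s$classifier)
  expect_lte(p$accuracyHi - p$accuracyLo, max(widths) + 1e-12)
})

test_that("exact McNemar p-values match the binomial closed form", {
  expect_equal(mcnemarExactP(0, 0), 1)
  expect_equal(mcnemarExactP(5, 0), 0.0625)
  expect_equal(mcnemarExactP(1, 0), 1)
  # independent computation over the full small-count grid
  for (b in 0:20) for (cc in 0:(20 - b)) {
    pRef <- if (b + cc == 0) 1 else
      min(1, 2 * sum(dbinom(0:min(b, cc), b + cc, 0.5)))
    expect_equal(mcnemarExactP(b, cc), pRef, info = paste(b, cc))
  }
})

test_that("McNemar construction dichotomizes per-instance majority correctness", {
  # 10 instances, 2 reps each; deep correct on 1-6, method correct on 1-4;
  # instance 10 tied for the method (counts as incorrect)
  reps <- rep(1:2, each = 10)
  id <- rep(sprintf("i%02d", 1:10), 2)
  truth <- rep(TRUE, 20)
  deepPred <- rep(c(rep(TRUE, 6), rep(FALSE, 4)), 2)
  methPred <- c(rep(TRUE, 4), rep(FALSE, 6),          # rep 1
                c(rep(TRUE, 4), rep(FALSE, 5), TRUE)) # rep 2: i10 split 1/1
  led <- mkLedger(rbind(
    data.frame(rep = reps, id = id, classifier = "deep", truth = truth,
               pred = deepPred),
    data.frame(rep = reps, id = id, classifier = "nb", truth = truth,
               pred = methPred)))
  m <- mcnemarVsDeep(led, "nb")
  expect_equal(m$b, 2)   # i5, i6: deep right, method wrong
  expect_equal(m$c, 0)
  expect_equal(m$p, mcnemarExactP(2, 0))
  expect_equal(m$ties, 1)
  # symmetry: swapping the roles swaps b and c, p unchanged
  m2 <- mcnemarVsDeep(led, "deep", deepName = "nb")
  expect_equal(m2$b, m$c)
  expect_equal(m2$c, m$b)
  expect_equal(m2$p, m$p)
  expect_error(mcnemarVsDeep(led, "absent"), "absent")
})
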