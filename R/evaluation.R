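#' Plan for repeated random-subsampling validation
#'
#' @param nRepetitions number of random train/test assortments
#'   (default 1000).
#' @param trainFraction proportion assigned to training (default 0.9).
#' @param seed integer; fully determines the split sequence.
#' @param stratified keep at least one instance of each class in every test
#'   set, with class counts apportioned by largest remainder.
#' @return a [SplitPlan-class].
#' @export
splitPlan <- function(nRepetitions = 1000L, trainFraction = 0.9, seed = 1L,
                      stratified = FALSE) {
  new("SplitPlan", nRepetitions = as.integer(nRepetitions),
      trainFraction = trainFraction, seed = as.integer(seed),
      stratified = stratified)
}

#' Draw the sequence of train/test partitions
#'
#' Test-set size is fixed to `floor(n * (1 - trainFraction))` (8 for n = 82
#' at 10 percent). Stratified plans apportion that total across classes by
#' largest remainder with a minimum of one per class (which can raise the
#' total when a class would otherwise get none).
#'
#' @param n number of subjects.
#' @param plan a [splitPlan()].
#' @param labels class labels, required when `plan@stratified`.
#' @return list of `nRepetitions` elements, each `list(train, test)` of
#'   disjoint index vectors covering `1:n`.
#' @export
makeSplits <- function(n, plan, labels = NULL) {
  stopifnot(is(plan, "SplitPlan"))
  if (n < 10L) stop("need at least 10 subjects to split", call. = FALSE)
  nTest <- max(1L, floor(n * (1 - plan@trainFraction)))
  if (plan@stratified) {
    if (is.null(labels) || length(labels) != n)
      stop("stratified splitting needs one label per subject", call. = FALSE)
    labels <- as.factor(labels)
    sizes <- table(labels)
    quota <- nTest * as.numeric(sizes) / n
    take <- pmax(1L, floor(quota))
    rem <- nTest - sum(take)
    if (rem > 0) {
      ord <- order(quota - floor(quota), decreasing = TRUE)
      take[ord[seq_len(min(rem, length(take)))]] <-
        take[ord[seq_len(min(rem, length(take)))]] + 1L
    }
    if (any(as.numeric(sizes) - take < 1L))
      stop("stratification impossible: class '",
           names(sizes)[which(as.numeric(sizes) - take < 1L)[1]],
           "' is too small for the requested test allocation", call. = FALSE)
    idxByClass <- split(seq_len(n), labels)
  }
  withSeed(deriveSeed(plan@seed, "splits"), {
    lapply(seq_len(plan@nRepetitions), function(r) {
      test <- if (plan@stratified) {
        sort(unlist(mapply(function(idx, k) sample(idx, k),
                           idxByClass, take, SIMPLIFY = FALSE),
                    use.names = FALSE))
      } else sort(sample.int(n, nTest))
      list(train = setdiff(seq_len(n), test), test = test)
    })
  })
}

#' Run the model-comparison harness
#'
#' Fits and evaluates every classifier on the same split sequence, so all
#' downstream comparisons (pooling, McNemar) are paired. Each repetition
#' refits from scratch with a repetition-derived seed. Under unstratified
#' splitting, a repetition whose training set contains a single outcome
#' class is re-drawn from a dedicated random stream (bounded retries,
#' count recorded in attribute `"redraws"`).
#'
#' @param specs list of [classifierSpec()] objects sharing one task.
#' @param x feature matrix (subjects x features).
#' @param y outcomes (logical for binary, numeric for continuous).
#' @param plan a [splitPlan()].
#' @return the repetition ledger: a data.frame with one row per test
#'   instance per repetition per classifier (`rep`, `id`, `classifier`,
#'   `truth`, `pred`), with attributes `task` and `redraws`.
#' @export
runHarness <- function(specs, x, y, plan) {
  if (!is.matrix(x)) x <- as.matrix(x)
  tasks <- unique(vapply(specs, function(s) s@task, ""))
  if (length(tasks) != 1L)
    stop("all specs must share one task", call. = FALSE)
  task <- tasks
  nms <- vapply(specs, function(s) s@name, "")
  if (anyDuplicated(nms)) stop("duplicate classifier names", call. = FALSE)
  n <- nrow(x)
  splits <- makeSplits(n, plan,
                       labels = if (plan@stratified) y else NULL)
  redraws <- 0L
  if (task == "binary" && !plan@stratified) {
    withSeed(deriveSeed(plan@seed, "redraw"), {
      for (r in seq_along(splits)) {
        tries <- 0L
        while (length(unique(y[splits[[r]]$train])) < 2L && tries < 100L) {
          test <- sort(sample.int(n, length(splits[[r]]$test)))
          splits[[r]] <- list(train = setdiff(seq_len(n), test), test = test)
          tries <- tries + 1L
        }
        redraws <- redraws + tries
      }
    })
  }
  ids <- rownames(x) %||% as.character(seq_len(n))
  out <- vector("list", length(splits) * length(specs))
  k <- 0L
  for (r in seq_along(splits)) {
    tr <- splits[[r]]$train; te <- splits[[r]]$test
    for (s in specs) {
      sRep <- s
      sRep@seed <- deriveSeed(s@seed, paste0("rep", r))
      model <- fitModel(sRep, x[tr, , drop = FALSE], y[tr])
      pred <- predictModel(model, x[te, , drop = FALSE])
      k <- k + 1L
      out[[k]] <- data.frame(rep = r, id = ids[te], classifier = s@name,
                             truth = y[te], pred = pred,
                             stringsAsFactors = FALSE)
    }
  }
  ledger <- do.call(rbind, out)
  rownames(ledger) <- NULL
  attr(ledger, "task") <- task
  attr(ledger, "redraws") <- redraws
  ledger
}

# per-repetition overall and class-wise accuracy, one row per rep x method
.perRepAccuracy <- function(ledger) {
  key <- interaction(ledger$rep, ledger$classifier, drop = TRUE)
  parts <- split(ledger, key)
  do.call(rbind, lapply(parts, function(d) {
    imp <- d$truth
    data.frame(rep = d$rep[1], classifier = d$classifier[1],
               accuracy = mean(d$pred == d$truth),
               improverAccuracy = if (any(imp)) mean(d$pred[imp]) else NA_real_,
               nonImproverAccuracy = if (any(!imp)) mean(!d$pred[!imp])
                                     else NA_real_)
  }))
}

.ciRow <- function(v) {
  v <- v[!is.na(v)]
  m <- mean(v)
  half <- 1.96 * stats::sd(v) / sqrt(length(v))
  if (!is.finite(half)) half <- 0
  c(mean = m, lo = m - half, hi = m + half)
}

#' Summarize a binary-task ledger
#'
#' Per-repetition accuracy is correct/test-size; Improver (non-Improver)
#' accuracy is computed among true Improvers (non-Improvers) in the test
#' set, skipping repetitions with an empty cell. Confidence intervals are
#' normal-approximation 95 percent intervals across repetitions
#' (`mean +/- 1.96 sd/sqrt(R)`).
#'
#' @param ledger a binary ledger from [runHarness()].
#' @return data.frame, one row per classifier, with accuracy, Improver
#'   accuracy and non-Improver accuracy plus their CI bounds.
#' @export
summarizeBinary <- function(ledger) {
  if (!nrow(ledger)) stop("empty ledger", call. = FALSE)
  pr <- .perRepAccuracy(ledger)
  do.call(rbind, lapply(split(pr, pr$classifier), function(d) {
    a <- .ciRow(d$accuracy); i <- .ciRow(d$improverAccuracy)
    ni <- .ciRow(d$nonImproverAccuracy)
    data.frame(classifier = d$classifier[1],
               accuracy = a["mean"], accuracyLo = a["lo"], accuracyHi = a["hi"],
               improverAccuracy = i["mean"], improverAccuracyLo = i["lo"],
               improverAccuracyHi = i["hi"],
               nonImproverAccuracy = ni["mean"],
               nonImproverAccuracyLo = ni["lo"],
               nonImproverAccuracyHi = ni["hi"],
               nReps = nrow(d), row.names = NULL)
  }))
}

# per-repetition RMSE, one row per rep x method
.perRepRmse <- function(ledger) {
  key <- interaction(ledger$rep, ledger$classifier, drop = TRUE)
  parts <- split(ledger, key)
  do.call(rbind, lapply(parts, function(d)
    data.frame(rep = d$rep[1], classifier = d$classifier[1],
               rmse = sqrt(mean((d$pred - d$truth)^2)))))
}

#' Summarize a continuous-task ledger
#'
#' Per-repetition RMSE over that repetition's test set, summarized as mean
#' and 95 percent CI across repetitions; the percent difference from the
#' deep learner is computed per repetition
#' (`(RMSE_method - RMSE_deep)/RMSE_deep * 100`) and then summarized.
#'
#' @param ledger a continuous ledger from [runHarness()].
#' @param deltaFrom reference classifier for the percent difference
#'   (default `"deep"`); `NULL` suppresses the column.
#' @return data.frame, one row per classifier.
#' @export
summarizeContinuous <- function(ledger, deltaFrom = "deep") {
  if (!nrow(ledger)) stop("empty ledger", call. = FALSE)
  pr <- .perRepRmse(ledger)
  if (!is.null(deltaFrom)) {
    if (!deltaFrom %in% pr$classifier)
      stop("reference classifier '", deltaFrom,
           "' absent from the ledger", call. = FALSE)
    ref <- pr[pr$classifier == deltaFrom, c("rep", "rmse")]
    names(ref)[2] <- "refRmse"
    pr <- merge(pr, ref, by = "rep")
    pr$pctDiff <- (pr$rmse - pr$refRmse) / pr$refRmse * 100
  }
  do.call(rbind, lapply(split(pr, pr$classifier), function(d) {
    r <- .ciRow(d$rmse)
    row <- data.frame(classifier = d$classifier[1], rmse = r["mean"],
                      rmseLo = r["lo"], rmseHi = r["hi"], nReps = nrow(d),
                      row.names = NULL)
    if (!is.null(deltaFrom)) {
      p <- .ciRow(d$pctDiff)
      row$pctDiffFromDeep <- p["mean"]
      row$pctDiffLo <- p["lo"]; row$pctDiffHi <- p["hi"]
    }
    row
  }))
}

#' Pool the shallow learners into one baseline
#'
#' Averages the per-repetition metric across the listed shallow methods,
#' then summarizes the per-repetition averages (mean and 95 percent CI); the
#' deep learner and the regression baseline are excluded by default. Because
#' averaging precedes summarizing, the pooled CI is at most as wide as the
#' widest member CI.
#'
#' @param ledger a ledger from [runHarness()].
#' @param methods classifiers to pool (default the six shallow learners).
#' @return a one-row data.frame shaped like the corresponding summary.
#' @export
poolShallow <- function(ledger, methods = shallowLearners()) {
  methods <- intersect(methods, unique(ledger$classifier))
  if (length(methods) < 2L)
    stop("need at least two shallow methods to pool", call. = FALSE)
  sub <- ledger[ledger$classifier %in% methods, ]
  if (attr(ledger, "task") == "binary") {
    pr <- .perRepAccuracy(sub)
    pooled <- stats::aggregate(
      pr[c("accuracy", "improverAccuracy", "nonImproverAccuracy")],
      by = list(rep = pr$rep), FUN = mean, na.rm = TRUE)
    a <- .ciRow(pooled$accuracy); i <- .ciRow(pooled$improverAccuracy)
    ni <- .ciRow(pooled$nonImproverAccuracy)
    data.frame(classifier = "pooled",
               accuracy = a["mean"], accuracyLo = a["lo"], accuracyHi = a["hi"],
               improverAccuracy = i["mean"], improverAccuracyLo = i["lo"],
               improverAccuracyHi = i["hi"],
               nonImproverAccuracy = ni["mean"],
               nonImproverAccuracyLo = ni["lo"],
               nonImproverAccuracyHi = ni["hi"],
               nReps = nrow(pooled), row.names = NULL)
  } else {
    pr <- .perRepRmse(sub)
    pooled <- stats::aggregate(pr["rmse"], by = list(rep = pr$rep), FUN = mean)
    r <- .ciRow(pooled$rmse)
    data.frame(classifier = "pooled", rmse = r["mean"], rmseLo = r["lo"],
               rmseHi = r["hi"], nReps = nrow(pooled), row.names = NULL)
  }
}

#' Exact two-tailed McNemar p-value from discordant counts
#'
#' `p = min(1, 2 P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`;
#' `p = 1` when there is no discordance.
#'
#' @param b,c discordant pair counts.
#' @return the exact two-tailed p-value.
#' @export
#' @examples
#' mcnemarExactP(5, 0)  # 0.0625
mcnemarExactP <- function(b, c) {
  if (b + c == 0L) return(1)
  min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
}

#' Paired McNemar comparison of a method against the deep learner
#'
#' Repeated holdout yields many test appearances per instance; each
#' instance is dichotomized per classifier as correct iff the fraction of
#' its test appearances predicted correctly exceeds one half (ties count as
#' incorrect and are reported). The discordant counts of the resulting
#' paired 2x2 table enter an exact two-tailed binomial test, appropriate
#' because discordant counts are small at these sample sizes.
#'
#' @param ledger a binary ledger from [runHarness()].
#' @param methodName the comparison classifier.
#' @param deepName the reference classifier (default `"deep"`).
#' @return list with `b` (reference correct, method incorrect), `c`
#'   (reference incorrect, method correct), `p`, `ties` (instances with a
#'   tied correctness fraction in either classifier) and `nInstances`.
#' @export
mcnemarVsDeep <- function(ledger, methodName, deepName = "deep") {
  for (nm in c(methodName, deepName))
    if (!nm %in% ledger$classifier)
      stop("classifier '", nm, "' absent from the ledger", call. = FALSE)
  corrFrac <- function(nm) {
    d <- ledger[ledger$classifier == nm, ]
    tapply(d$pred == d$truth, d$id, mean)
  }
  fDeep <- corrFrac(deepName); fMeth <- corrFrac(methodName)
  ids <- sort(unique(ledger$id))
  if (!all(ids %in% names(fDeep)) || !all(ids %in% names(fMeth)))
    stop("an instance never appeared in any test set; ",
         "increase the number of repetitions", call. = FALSE)
  okDeep <- fDeep[ids] > 0.5
  okMeth <- fMeth[ids] > 0.5
  ties <- sum(fDeep[ids] == 0.5) + sum(fMeth[ids] == 0.5)
  b <- sum(okDeep & !okMeth)
  c_ <- sum(!okDeep & okMeth)
  list(b = b, c = c_, p = mcnemarExactP(b, c_), ties = ties,
       nInstances = length(ids))
}
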