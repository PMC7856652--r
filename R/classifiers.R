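#' Create a classifier specification
#'
#' A uniform description of one learner for the comparison harness. Shallow
#' learners delegate to established implementations (e1071, randomForest,
#' rpart); the K* similarity and the deep multilayer perceptron (Adam
#' optimizer, rectified-linear hidden units, single output neuron) are
#' implemented in this package. For the continuous task, learners that
#' require nominal outcomes (`naive_bayes`, `adaboost`, `j48`,
#' `random_forest`) are routed through [binContinuousOutcome()] and predict
#' bin midpoints; `linear`, `svm_poly`, `kstar` and `deep` regress directly.
#'
#' @param name one of `"logistic"`, `"linear"`, `"naive_bayes"`,
#'   `"svm_poly"`, `"kstar"`, `"adaboost"`, `"j48"`, `"random_forest"`,
#'   `"deep"`, or a calibration baseline `"majority"`, `"coin"`,
#'   `"constant_mean"`.
#' @param task `"binary"` (Improver vs non-Improver) or `"continuous"`
#'   (BPRS change).
#' @param params name-specific hyperparameters. Recognized entries:
#'   `exponent` (svm_poly, default 1), `blend` (kstar, default 0.2),
#'   `nRounds` (adaboost, default 50), `ntree` (random_forest, default 500),
#'   `hidden` (deep; default `c(8, 32, 16, 8)`, use `c(128, 64, 8)` after a
#'   252-wide voxel input), `lr` (1e-3), `epochs` (500), `batchSize` (32),
#'   `nBins` (nominal routing of the continuous task, default 10).
#' @param seed integer seed for any stochastic element of the fit.
#' @return a [ClassifierSpec-class].
#' @export
classifierSpec <- function(name, task = c("binary", "continuous"),
                           params = list(), seed = 1L) {
  task <- match.arg(task)
  known <- c("logistic", "linear", "naive_bayes", "svm_poly", "kstar",
             "adaboost", "j48", "random_forest", "deep",
             "majority", "coin", "constant_mean")
  if (!name %in% known)
    stop("unknown classifier '", name, "'", call. = FALSE)
  if (name == "logistic" && task != "binary")
    stop("logistic is the binary regression baseline; use 'linear' for the ",
         "continuous task", call. = FALSE)
  if (name == "linear" && task != "continuous")
    stop("linear is the continuous regression baseline; use 'logistic' for ",
         "the binary task", call. = FALSE)
  new("ClassifierSpec", name = name, task = task, params = params,
      seed = as.integer(seed))
}

.NOMINAL_ONLY <- c("naive_bayes", "adaboost", "j48", "random_forest",
                   "majority", "coin")
.SHALLOW_SIX <- c("naive_bayes", "svm_poly", "kstar", "adaboost", "j48",
                  "random_forest")

#' Shallow-learner roster used for pooling
#'
#' The six shallow methods compared against the deep learner; the regression
#' baseline is listed separately and is excluded from pooling by default.
#' @return character vector of classifier names.
#' @export
shallowLearners <- function() .SHALLOW_SIX

#' Equal-width binning of a continuous outcome
#'
#' Bins span the `[min, max]` of the supplied (training) values; labels run
#' `0 .. nBins - 1`; a bin's representative value for error computation is
#' its midpoint. Values outside the range (e.g. test values) clamp to the
#' edge bins.
#'
#' @param deltas numeric training values.
#' @param nBins number of bins (default 10).
#' @return list with `edges` (length `nBins + 1`), `mids`, and `labels`
#'   (integer bin of each input value).
#' @export
#' @examples
#' b <- binContinuousOutcome(c(-20, -3, 0, 7, 20), nBins = 10)
#' b$labels  # 0 4 5 6 9
binContinuousOutcome <- function(deltas, nBins = 10L) {
  stopifnot(nBins >= 2L || length(unique(deltas)) == 1L)
  lo <- min(deltas); hi <- max(deltas)
  if (hi - lo < .Machine$double.eps^0.5) {
    warning("zero range; collapsing to a single degenerate bin")
    return(list(edges = c(lo, lo), mids = lo,
                labels = rep(0L, length(deltas)), nBins = 1L))
  }
  edges <- seq(lo, hi, length.out = nBins + 1L)
  list(edges = edges, mids = (edges[-1L] + edges[-(nBins + 1L)]) / 2,
       labels = assignBins(deltas, edges), nBins = as.integer(nBins))
}

#' @rdname binContinuousOutcome
#' @param values numeric values to assign.
#' @param edges bin edges as returned by `binContinuousOutcome()`.
#' @export
assignBins <- function(values, edges) {
  nBins <- length(edges) - 1L
  if (nBins < 1L) return(rep(0L, length(values)))
  w <- (edges[nBins + 1L] - edges[1L]) / nBins
  lab <- floor((values - edges[1L]) / w)
  as.integer(pmin(pmax(lab, 0L), nBins - 1L))
}

# AdaBoost (SAMME) over depth-1 rpart stumps; multiclass-capable so the
# binned continuous task routes through the same code
.adaboostFit <- function(x, y, nRounds = 50L) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  df <- data.frame(x, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1L, minsplit = 2L, cp = -1,
                               xval = 0L)
  for (t in seq_len(nRounds)) {
    dat <- cbind(df, .y = y)
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / K) break
    alpha <- if (err <= 0) 10 else log((1 - err) / err) + log(K - 1)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 0) break
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

.adaboostPredict <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  votes <- matrix(0, nrow(df), length(fit$levels),
                  dimnames = list(NULL, fit$levels))
  for (t in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[t]], df, type = "class")
    ij <- cbind(seq_len(nrow(df)), match(as.character(pred), fit$levels))
    votes[ij] <- votes[ij] + fit$alphas[t]
  }
  factor(fit$levels[max.col(votes, ties.method = "first")],
         levels = fit$levels)
}

.checkTrainInputs <- function(spec, x, y) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (spec@task == "binary") {
    y <- as.logical(y)
    if (length(unique(y)) < 2L &&
        !spec@name %in% c("majority", "coin"))
      stop("degenerate fit: a single outcome class in the training set",
           call. = FALSE)
  }
  list(x = x, y = y)
}

#' Fit a classifier
#'
#' @param spec a [classifierSpec()].
#' @param x numeric feature matrix (subjects x features), e.g. from
#'   [featureMatrix()].
#' @param y outcomes: logical Improver flags for the binary task, numeric
#'   BPRS changes for the continuous task.
#' @param ... unused.
#' @return a [TrainedModel-class].
#' @rdname fitModel
#' @export
setMethod("fitModel", "ClassifierSpec", function(spec, x, y, ...) {
  inp <- .checkTrainInputs(spec, x, y)
  x <- inp$x; y <- inp$y
  p <- spec@params
  nm <- spec@name
  binaryFac <- function(v) factor(ifelse(v, "Improver", "nonImprover"),
                                  levels = c("nonImprover", "Improver"))
  fit <- if (spec@task == "continuous" && nm %in% .NOMINAL_ONLY &&
             nm != "coin") {
    # nominal-only learners see the binned outcome and predict midpoints
    bins <- binContinuousOutcome(y, p$nBins %||% 10L)
    yf <- factor(bins$labels)   # empty bins carry no level

    inner <- switch(nm,
      naive_bayes = list(nb = e1071::naiveBayes(x, yf)),
      adaboost = withSeed(deriveSeed(spec@seed, "adaboost"),
                          list(ab = .adaboostFit(x, yf, p$nRounds %||% 50L))),
      j48 = list(tree = rpart::rpart(
        .y ~ ., data = data.frame(x, .y = yf, check.names = FALSE),
        method = "class", parms = list(split = "information"),
        control = rpart::rpart.control(xval = 0L))),
      random_forest = withSeed(deriveSeed(spec@seed, "rf"),
                               list(rf = randomForest::randomForest(
                                 x, yf, ntree = p$ntree %||% 500L))),
      majority = list(constant = names(which.max(table(yf)))))
    c(inner, list(bins = bins))
  } else switch(nm,
    logistic = {
      df <- data.frame(x, .y = as.numeric(y), check.names = FALSE)
      list(glm = suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial())))
    },
    linear = list(lm = stats::lm(.y ~ ., data = data.frame(
      x, .y = y, check.names = FALSE))),
    naive_bayes = list(nb = e1071::naiveBayes(x, binaryFac(y))),
    svm_poly = withSeed(deriveSeed(spec@seed, "svm"), {
      if (spec@task == "binary")
        list(svm = e1071::svm(x, binaryFac(y), kernel = "polynomial",
                              degree = p$exponent %||% 1L, coef0 = 1))
      else
        list(svm = e1071::svm(x, y, kernel = "polynomial",
                              degree = p$exponent %||% 1L, coef0 = 1,
                              type = "eps-regression"))
    }),
    kstar = list(kstar = .kstarFit(x, y, p$blend %||% 0.2, spec@task)),
    adaboost = withSeed(deriveSeed(spec@seed, "adaboost"),
                        list(ab = .adaboostFit(x, binaryFac(y),
                                               p$nRounds %||% 50L))),
    j48 = list(tree = rpart::rpart(
      .y ~ ., data = data.frame(x, .y = binaryFac(y), check.names = FALSE),
      method = "class", parms = list(split = "information"),
      control = rpart::rpart.control(xval = 0L))),
    random_forest = withSeed(deriveSeed(spec@seed, "rf"),
                             list(rf = randomForest::randomForest(
                               x, binaryFac(y), ntree = p$ntree %||% 500L))),
    deep = {
      hidden <- p$hidden %||% (if (ncol(x) >= 64L) c(128L, 64L, 8L)
                               else c(8L, 32L, 16L, 8L))
      # continuous targets are standardized for training and predictions
      # mapped back, so the learning rate is scale-free
      yC <- as.numeric(y)
      yMean <- 0; ySd <- 1
      if (spec@task == "continuous") {
        yMean <- mean(yC); ySd <- stats::sd(yC)
        if (!is.finite(ySd) || ySd < 1e-12) ySd <- 1
        yC <- (yC - yMean) / ySd
      }
      list(mlp = .mlpTrain(x, yC, hidden = hidden,
                           task = spec@task, lr = p$lr %||% 1e-3,
                           epochs = p$epochs %||% 500L,
                           batchSize = p$batchSize %||% 32L,
                           seed = spec@seed,
                           patience = p$patience %||% 20L),
           yMean = yMean, ySd = ySd)
    },
    majority = list(constant = if (mean(y) >= 0.5) TRUE else FALSE),
    coin = list(seed = deriveSeed(spec@seed, "coin"), task = spec@task),
    constant_mean = list(constant = mean(y)),
    stop("unhandled classifier '", nm, "'", call. = FALSE))
  new("TrainedModel", spec = spec, fit = fit, featureNames = colnames(x))
})

#' Predict from a fitted classifier
#'
#' Binary deep predictions threshold the sigmoid output at 0.5; nominal
#' learners on the continuous task return their predicted bin's midpoint.
#'
#' @param model a [TrainedModel-class].
#' @param x feature matrix with the training column layout.
#' @param ... unused.
#' @return logical (binary task) or numeric (continuous task), one value
#'   per row.
#' @rdname predictModel
#' @export
setMethod("predictModel", "TrainedModel", function(model, x, ...) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!identical(colnames(x), model@featureNames))
    stop("feature layout mismatch with the training matrix", call. = FALSE)
  f <- model@fit
  nm <- model@spec@name
  task <- model@spec@task
  if (task == "continuous" && nm %in% setdiff(.NOMINAL_ONLY, "coin")) {
    lab <- if (nm == "majority") rep(f$constant, nrow(x)) else {
      pred <- switch(nm,
        naive_bayes = predict(f$nb, x),
        adaboost = .adaboostPredict(f$ab, x),
        j48 = predict(f$tree, data.frame(x, check.names = FALSE),
                      type = "class"),
        random_forest = predict(f$rf, x))
      as.character(pred)
    }
    idx <- as.integer(lab) + 1L
    return(f$bins$mids[pmin(pmax(idx, 1L), length(f$bins$mids))])
  }
  switch(nm,
    logistic = unname(predict(f$glm, data.frame(x, check.names = FALSE),
                              type = "response") > 0.5),
    linear = unname(predict(f$lm, data.frame(x, check.names = FALSE))),
    naive_bayes = predict(f$nb, x) == "Improver",
    svm_poly = {
      pr <- predict(f$svm, x)
      if (task == "binary") pr == "Improver" else unname(pr)
    },
    kstar = .kstarPredict(f$kstar, x),
    adaboost = .adaboostPredict(f$ab, x) == "Improver",
    j48 = predict(f$tree, data.frame(x, check.names = FALSE),
                  type = "class") == "Improver",
    random_forest = predict(f$rf, x) == "Improver",
    deep = {
      out <- .mlpPredictRaw(f$mlp, x)
      if (task == "binary") out > 0.5 else out * f$ySd + f$yMean
    },
    majority = rep(f$constant, nrow(x)),
    coin = withSeed(f$seed + nrow(x), runif(nrow(x)) > 0.5),
    constant_mean = rep(f$constant, nrow(x)),
    stop("unhandled classifier '", nm, "'", call. = FALSE))
})

#' Raw sigmoid/linear output of the deep model
#'
#' @param model a deep [TrainedModel-class].
#' @param x feature matrix.
#' @return numeric network output before thresholding (in `[0, 1]` for the
#'   binary task).
#' @export
deepOutput <- function(model, x) {
  stopifnot(model@spec@name == "deep")
  if (!is.matrix(x)) x <- as.matrix(x)
  .mlpPredictRaw(model@fit$mlp, x)
}

#' Post-nonlinearity neuron activations of the deep model
#'
#' @param model a deep [TrainedModel-class].
#' @param x feature matrix (instances x features).
#' @param ... unused.
#' @return list with `input` (the instances), `hidden` (one post-ReLU
#'   matrix per hidden layer) and `output`.
#' @rdname activations
#' @export
setMethod("activations", "TrainedModel", function(model, x, ...) {
  if (model@spec@name != "deep")
    stop("activation capture is only supported for the deep model",
         call. = FALSE)
  if (!is.matrix(x)) x <- as.matrix(x)
  .mlpActivations(model@fit$mlp, x)
})

#' Choose the polynomial-kernel exponent by accuracy plateau
#'
#' Evaluates exponents in ascending order with the repeated-holdout harness
#' and returns the smallest exponent whose successor improves mean holdout
#' accuracy by less than `plateauTol` (default half a percentage point). If
#' accuracy keeps rising through the whole list the last exponent is
#' returned.
#'
#' @param x,y training features and binary outcomes.
#' @param exponents ascending integer exponents starting at 1.
#' @param plateauTol minimum mean-accuracy gain to keep increasing.
#' @param plan a [splitPlan()] controlling the holdout repetitions.
#' @param seed seed for the per-exponent classifier fits.
#' @return the chosen exponent, with the per-exponent mean accuracies in
#'   attribute `"accuracies"`.
#' @export
svmExponentSearch <- function(x, y, exponents = 1:5, plateauTol = 0.005,
                              plan = splitPlan(nRepetitions = 50L),
                              seed = 1L) {
  if (!length(exponents)) stop("empty exponent list", call. = FALSE)
  if (is.unsorted(exponents) || exponents[1] != 1L)
    stop("exponents must ascend from 1", call. = FALSE)
  accs <- rep(NA_real_, length(exponents))
  for (i in seq_along(exponents)) {
    spec <- classifierSpec("svm_poly", "binary",
                           params = list(exponent = exponents[i]), seed = seed)
    led <- runHarness(list(spec), x, y, plan)
    accs[i] <- mean(.perRepAccuracy(led)$accuracy)
    if (i > 1L && accs[i] - accs[i - 1L] < plateauTol)
      return(structure(exponents[i - 1L], accuracies = accs))
  }
  structure(exponents[length(exponents)], accuracies = accs)
}
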