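# Rule extraction: binarize activations, cover, translate to DNF rules.

# information gain of the binary split (x > t) on binary labels
.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.infoGain <- function(x, y, t) {
  n <- length(y)
  hi <- x > t
  if (!any(hi) || all(hi)) return(0)
  h0 <- .entropy(table(y) / n)
  h1 <- .entropy(table(y[hi]) / sum(hi))
  h2 <- .entropy(table(y[!hi]) / sum(!hi))
  h0 - (sum(hi) / n) * h1 - (sum(!hi) / n) * h2
}

# candidate thresholds: midpoints between consecutive sorted unique values
.thresholdCandidates <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(numeric(0))
  (u[-1L] + u[-length(u)]) / 2
}

#' Top information-gain thresholds per feature
#'
#' Scans the midpoints between consecutive sorted values of each feature and
#' ranks them by the information gain of the induced binary split on the
#' labels. These thresholds define the input-layer indicator nodes of the
#' activation tables.
#'
#' @param x feature matrix (instances x features).
#' @param y binary labels.
#' @param topK thresholds retained per feature (default 3).
#' @return data.frame with `feature`, `threshold`, `gain`, best first
#'   within each feature.
#' @export
infoGainThresholds <- function(x, y, topK = 3L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  out <- lapply(colnames(x), function(f) {
    cand <- .thresholdCandidates(x[, f])
    if (!length(cand)) return(NULL)
    g <- vapply(cand, .infoGain, 0, x = x[, f], y = y)
    ord <- order(g, decreasing = TRUE)[seq_len(min(topK, length(cand)))]
    data.frame(feature = f, threshold = cand[ord], gain = g[ord])
  })
  do.call(rbind, out)
}

# full binary node-activation matrix for a set of instances
.activationMatrix <- function(model, x, neurons) {
  act <- activations(model, x)
  cols <- matrix(0, nrow(x), nrow(neurons))
  for (j in seq_len(nrow(neurons))) {
    cols[, j] <- if (neurons$layer[j] == "input") {
      as.numeric(x[, neurons$feature[j]] > neurons$threshold[j])
    } else {
      l <- as.integer(sub("^h", "", neurons$layer[j]))
      as.numeric(act$hidden[[l]][, neurons$unit[j]] > 0)
    }
  }
  colnames(cols) <- neurons$id
  cols
}

#' Build the class-split binary activation tables
#'
#' A hidden neuron is "active" for an instance when its post-ReLU output is
#' strictly positive. Continuous input features have no native on/off
#' state, so each feature contributes indicator nodes `feature > t` with
#' thresholds drawn from a per-feature information-gain scan on the
#' training labels (top `inputTopK` thresholds each); this is what lets the
#' cover solution translate back into threshold rules over the inputs.
#' Rows are routed to `xPlus`/`xMinus` by label.
#'
#' @param model a deep [TrainedModel-class].
#' @param x training feature matrix.
#' @param labels logical Improver flags, one per row of `x`.
#' @param inputTopK indicator thresholds per input feature (default 3).
#' @param includeInput include the input indicator nodes alongside hidden
#'   units (default TRUE; set FALSE for a hidden-only cover).
#' @param neurons an existing binarization spec (the `@neurons` table of a
#'   previous [ActivationTable-class]) to reuse instead of re-scanning
#'   thresholds; useful for applying a fixed spec to new instances or
#'   permuted labels.
#' @return an [ActivationTable-class].
#' @export
binarizeActivations <- function(model, x, labels, inputTopK = 3L,
                                includeInput = TRUE, neurons = NULL) {
  if (model@spec@name != "deep")
    stop("activation binarization requires the deep model", call. = FALSE)
  if (!is.matrix(x)) x <- as.matrix(x)
  labels <- as.logical(labels)
  act <- activations(model, x)
  if (is.null(neurons)) {
    if (includeInput) {
      ig <- infoGainThresholds(x, labels, topK = inputTopK)
      if (!is.null(ig) && nrow(ig))
        neurons <- DataFrame(
          id = sprintf("in:%s>%.6g", ig$feature, ig$threshold),
          layer = "input", feature = ig$feature, unit = NA_integer_,
          threshold = ig$threshold, direction = ">")
    }
    for (l in seq_along(act$hidden)) {
      nh <- ncol(act$hidden[[l]])
      hdf <- DataFrame(id = sprintf("h%d:%d", l, seq_len(nh)),
                       layer = paste0("h", l), feature = NA_character_,
                       unit = seq_len(nh), threshold = 0, direction = ">")
      neurons <- if (is.null(neurons)) hdf else rbind(neurons, hdf)
    }
  }
  M <- .activationMatrix(model, x, neurons)
  rownames(M) <- rownames(x) %||% as.character(seq_len(nrow(x)))
  degenerate <- apply(M, 2L, function(col) length(unique(col)) == 1L)
  if (all(degenerate))
    warning("all node activations are constant across instances")
  new("ActivationTable", xPlus = M[labels, , drop = FALSE],
      xMinus = M[!labels, , drop = FALSE], neurons = neurons)
}

# best single threshold literal agreeing with a binary pattern
.surrogateLiteral <- function(x, pattern) {
  best <- list(agreement = -Inf)
  for (f in colnames(x)) {
    for (t in .thresholdCandidates(x[, f])) {
      agrGt <- mean((x[, f] > t) == pattern)
      agrLe <- mean((x[, f] <= t) == pattern)
      if (agrGt > best$agreement)
        best <- list(feature = f, op = ">", threshold = t, agreement = agrGt)
      if (agrLe > best$agreement)
        best <- list(feature = f, op = "<=", threshold = t, agreement = agrLe)
    }
  }
  if (is.finite(best$agreement)) best else NULL
}

.literalFires <- function(lit, x) {
  v <- x[, lit$feature]
  if (lit$op == ">") v > lit$threshold else v <= lit$threshold
}

.ruleFires <- function(rule, x) {
  fire <- rep(TRUE, nrow(x))
  for (lit in rule$literals) fire <- fire & .literalFires(lit, x)
  fire
}

# ruleset prediction: first firing rule in rank order decides, else default
.rulesPredict <- function(ruleList, defaultClass, x) {
  pred <- rep(defaultClass == "Improver", nrow(x))
  decided <- rep(FALSE, nrow(x))
  for (r in ruleList) {
    fire <- .ruleFires(r, x) & !decided
    pred[fire] <- r$class == "Improver"
    decided <- decided | fire
  }
  pred
}

#' Translate a cover solution into DNF threshold rules
#'
#' Selected input-layer indicator nodes translate directly into threshold
#' literals (`A+` nodes assert Improver, `A-` nodes non-Improver); selected
#' hidden nodes are translated through a single-literal surrogate: the
#' input-feature threshold whose indicator agrees best with that node's
#' activation pattern over the training instances (agreement reported).
#' Rules are ranked by training-label accuracy when read as two-sided
#' classifiers; rules whose marginal contribution to fidelity with the deep
#' model is negative are dropped, and the returned set is the minimal
#' ranked prefix retaining at least `fidelityKeep` of the full set's
#' fidelity - only the most predictive rules are reported.
#'
#' @param cover a [solveSetCover()] solution.
#' @param table the [ActivationTable-class] the cover was solved on.
#' @param model the deep [TrainedModel-class].
#' @param x training feature matrix (instances x features).
#' @param labels logical Improver flags for `x`.
#' @param fidelityKeep fraction of full fidelity the pruned prefix must
#'   retain (default 0.95).
#' @return a [RuleSet-class].
#' @export
extractRules <- function(cover, table, model, x, labels,
                         fidelityKeep = 0.95) {
  if (!is.matrix(x)) x <- as.matrix(x)
  labels <- as.logical(labels)
  deepPred <- predictModel(model, x)
  defaultClass <- if (mean(deepPred) >= 0.5) "Improver" else "non-Improver"
  neurons <- table@neurons
  M <- .activationMatrix(model, x, neurons)
  mkRule <- function(j, cls) {
    if (neurons$layer[j] == "input") {
      lit <- list(feature = neurons$feature[j], op = ">",
                  threshold = neurons$threshold[j])
      agr <- 1
    } else {
      sur <- .surrogateLiteral(x, M[, j] > 0)
      if (is.null(sur)) return(NULL)
      lit <- sur[c("feature", "op", "threshold")]
      agr <- sur$agreement
    }
    # node active predicts cls for A+ nodes; for A- nodes the literal marks
    # non-Improver activation
    fires <- .literalFires(lit, x)
    predImp <- if (cls == "Improver") fires else !fires
    acc <- mean(predImp == labels)
    list(class = cls, literals = list(lit), accuracy = acc, agreement = agr,
         node = neurons$id[j])
  }
  ruleList <- c(lapply(cover$aPlus, mkRule, cls = "Improver"),
                lapply(cover$aMinus, mkRule, cls = "non-Improver"))
  ruleList <- Filter(Negate(is.null), ruleList)
  if (!length(ruleList))
    return(new("RuleSet", rules = list(), aPlus = as.integer(cover$aPlus),
               aMinus = as.integer(cover$aMinus), fidelity = 0, coverage = 0,
               defaultClass = defaultClass))
  ruleList <- ruleList[order(vapply(ruleList, `[[`, 0, "accuracy"),
                             decreasing = TRUE)]
  # greedy prefix, dropping rules that would lower fidelity (keeps the
  # fidelity curve monotone non-decreasing)
  kept <- list(); fid <- numeric(0)
  cur <- mean(.rulesPredict(list(), defaultClass, x) == deepPred)
  for (r in ruleList) {
    trial <- c(kept, list(r))
    f <- mean(.rulesPredict(trial, defaultClass, x) == deepPred)
    if (f >= cur) { kept <- trial; cur <- f; fid <- c(fid, f) }
  }
  if (!length(kept))
    return(new("RuleSet", rules = list(), aPlus = as.integer(cover$aPlus),
               aMinus = as.integer(cover$aMinus), fidelity = cur, coverage = 0,
               defaultClass = defaultClass))
  fullFid <- fid[length(fid)]
  nKeep <- which(fid >= fidelityKeep * fullFid)[1]
  kept <- kept[seq_len(nKeep)]
  # with the prefix fixed, the fallback class is re-chosen to agree best
  # with the deep model on the instances no rule covers (a one-rule set
  # then reads two-sided: "feature > t -> Improver, else non-Improver")
  fidBy <- vapply(c("Improver", "non-Improver"), function(dc)
    mean(.rulesPredict(kept, dc, x) == deepPred), 0)
  defaultClass <- names(fidBy)[which.max(fidBy)]
  fires <- Reduce(`|`, lapply(kept, .ruleFires, x = x))
  new("RuleSet", rules = kept, aPlus = as.integer(cover$aPlus),
      aMinus = as.integer(cover$aMinus), fidelity = unname(max(fidBy)),
      coverage = mean(fires), defaultClass = defaultClass)
}

#' Situate single-feature rule thresholds between group means
#'
#' For each single-literal rule, reports the healthy-control and patient
#' means of the rule's feature with 95 percent CIs, and whether the
#' threshold is intermediate to the two means.
#'
#' @param ruleset a [RuleSet-class].
#' @param hcFeatures,patientFeatures reference feature matrices
#'   (subjects x features) on the same scale as the rule thresholds.
#' @return data.frame with one row per single-literal rule.
#' @export
ruleContextReport <- function(ruleset, hcFeatures, patientFeatures) {
  single <- Filter(function(r) length(r$literals) == 1L, ruleset@rules)
  if (!length(single)) return(data.frame())
  meanCi <- function(v) {
    m <- mean(v); half <- 1.96 * stats::sd(v) / sqrt(length(v))
    c(m, m - half, m + half)
  }
  do.call(rbind, lapply(single, function(r) {
    f <- r$literals[[1]]$feature
    if (!f %in% colnames(hcFeatures) || !f %in% colnames(patientFeatures))
      stop("feature '", f, "' absent from a reference matrix", call. = FALSE)
    t0 <- r$literals[[1]]$threshold
    hc <- meanCi(hcFeatures[, f]); pat <- meanCi(patientFeatures[, f])
    data.frame(feature = f, threshold = t0, class = r$class,
               hcMean = hc[1], hcLo = hc[2], hcHi = hc[3],
               patientMean = pat[1], patientLo = pat[2], patientHi = pat[3],
               intermediate = t0 > min(hc[1], pat[1]) &
                 t0 < max(hc[1], pat[1]))
  }))
}
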