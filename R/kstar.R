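# K* instance-based classification on an entropic transformation distance.
#
# The similarity between a query instance and a stored instance is the
# negative log of the probability that a random walk of elementary
# transformations in feature space turns one into the other. For real-valued
# features the single-step transformation density is exponential in the
# absolute difference with a per-feature scale x0; the blend parameter sets
# x0 through the "sphere of influence": the effective number of candidate
# instances contributing transformation mass is m0 + blend * (N - m0),
# where m0 counts the instances at the minimum distance and N is the
# candidate-set size (blend 0 would concentrate all mass on the nearest
# instances, blend 1 spreads it uniformly).

# per-feature scale: solve sum_c exp(-(d_c - min d)/x0) = m0 + blend*(N - m0)
.kstarScale <- function(d, blend) {
  d <- d - min(d)
  N <- length(d)
  m0 <- sum(d < 1e-12)
  if (m0 == N) return(Inf)
  target <- m0 + blend * (N - m0)
  g <- function(x0) sum(exp(-d / x0))
  hi <- 1
  while (g(hi) < target && hi < 1e12) hi <- hi * 2
  lo <- 1e-12
  for (i in 1:80) {
    mid <- sqrt(lo * hi)    # bisect in log space
    if (g(mid) < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# transformation probabilities from query `a` to every row of `train`
.kstarProbs <- function(a, train, blend) {
  logq <- rep(0, nrow(train))
  for (f in seq_len(ncol(train))) {
    d <- abs(train[, f] - a[f])
    x0 <- .kstarScale(d, blend)
    if (is.finite(x0)) logq <- logq - d / x0
  }
  w <- exp(logq - max(logq))
  list(p = w / sum(w), logq = logq, logZ = max(logq) + log(sum(exp(logq - max(logq)))))
}

#' K* entropic similarity between two instances
#'
#' Returns `-ln P*(b | a)`, where `P*` is the probability of all
#' transformational paths from `a` to `b` under the per-feature exponential
#' transformation model, normalized over the candidate set `train` (which
#' should contain `b`). Smaller values mean more similar; the
#' self-transformation `b = a` attains the minimum over any fixed candidate
#' set.
#'
#' @param a,b numeric instances sharing the feature layout of `train`.
#' @param train numeric candidate matrix (instances x features) defining the
#'   transformation normalizer and the blend spheres.
#' @param blend sphere-of-influence blend parameter in `(0, 1]`
#'   (default 0.2).
#' @return nonnegative similarity (a negative log probability).
#' @export
kstarSimilarity <- function(a, b, train, blend = 0.2) {
  stopifnot(is.matrix(train), length(a) == ncol(train),
            length(b) == ncol(train))
  if (blend <= 0)
    stop("blend = 0 degenerates the transformation distribution", call. = FALSE)
  pr <- .kstarProbs(a, train, blend)
  logqB <- 0
  for (f in seq_len(ncol(train))) {
    d <- abs(train[, f] - a[f])
    x0 <- .kstarScale(d, blend)
    if (is.finite(x0)) logqB <- logqB - abs(b[f] - a[f]) / x0
  }
  -(logqB - pr$logZ)
}

.kstarFit <- function(x, y, blend, task) {
  list(x = x, y = y, blend = blend, task = task)
}

.kstarPredict <- function(fit, xnew) {
  out <- if (fit$task == "binary") logical(nrow(xnew)) else numeric(nrow(xnew))
  for (i in seq_len(nrow(xnew))) {
    pr <- .kstarProbs(xnew[i, ], fit$x, fit$blend)
    if (fit$task == "binary") {
      # class vote: summed transformation probability per class
      out[i] <- sum(pr$p[fit$y]) > sum(pr$p[!fit$y])
    } else {
      out[i] <- sum(pr$p * fit$y)
    }
  }
  out
}
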