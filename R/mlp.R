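# Multilayer perceptron with Adam, in plain matrix code.
#
# Small enough problems (a few hundred subjects, 4 or 252 features) that
# vectorized base R is fast; no GPU path. Hidden units are rectified-linear;
# the output layer is a single neuron, sigmoid for the binary task and
# linear for the continuous task. Every neuron's post-nonlinearity output is
# recomputable for any instance, which the rule-extraction stage relies on.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.mlpInit <- function(sizes, seed) {
  withSeed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      fanIn <- sizes[l]
      W[[l]] <- matrix(rnorm(fanIn * sizes[l + 1L], sd = sqrt(2 / fanIn)),
                       fanIn, sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

.mlpForward <- function(net, x, task) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- x
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) pmax(Z[[l]], 0) else
      if (task == "binary") .sigmoid(Z[[l]]) else Z[[l]]
  }
  list(A = A, Z = Z)
}

.mlpTrain <- function(x, y, hidden, task, lr = 1e-3, epochs = 500L,
                      batchSize = 32L, seed = 1L, patience = 20L,
                      tol = 1e-4) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(is.finite(x)))
  n <- nrow(x)
  sizes <- c(ncol(x), hidden, 1L)
  net <- .mlpInit(sizes, deriveSeed(seed, "mlp-init"))
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  bestLoss <- Inf; stall <- 0L; lossTrace <- numeric(0)
  withSeed(deriveSeed(seed, "mlp-batches"), {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batchSize - 1L, n)]
        xb <- x[idx, , drop = FALSE]; yb <- y[idx]
        fw <- .mlpForward(net, xb, task)
        out <- fw$A[[L + 1L]][, 1L]
        nb <- length(idx)
        if (task == "binary") {
          p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
          epochLoss <- epochLoss - sum(yb * log(p) + (1 - yb) * log(1 - p))
          dZ <- matrix((out - yb) / nb, nb, 1L)
        } else {
          epochLoss <- epochLoss + sum((out - yb)^2)
          dZ <- matrix(2 * (out - yb) / nb, nb, 1L)
        }
        step <- step + 1L
        for (l in rev(seq_len(L))) {
          dW <- crossprod(fw$A[[l]], dZ)
          db <- colSums(dZ)
          if (l > 1L) {
            dA <- tcrossprod(dZ, net$W[[l]])
            dZ <- dA * (fw$Z[[l - 1L]] > 0)
          }
          # Adam update with bias correction
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * dW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * dW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * db
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * db^2
          c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
          net$W[[l]] <- net$W[[l]] - lr * (mW[[l]] / c1) /
            (sqrt(vW[[l]] / c2) + eps)
          net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / c1) /
            (sqrt(vb[[l]] / c2) + eps)
        }
      }
      epochLoss <- epochLoss / n
      lossTrace <- c(lossTrace, epochLoss)
      if (bestLoss - epochLoss > tol) {
        bestLoss <- epochLoss; stall <- 0L
      } else stall <- stall + 1L
      if (stall >= patience) break
    }
  })
  list(net = net, sizes = sizes, task = task, finalLoss = lossTrace[length(lossTrace)],
       epochsRun = length(lossTrace), lossTrace = lossTrace)
}

.mlpPredictRaw <- function(fit, x) {
  fw <- .mlpForward(fit$net, x, fit$task)
  fw$A[[length(fit$net$W) + 1L]][, 1L]
}

# post-nonlinearity outputs of every input and hidden neuron, per instance
.mlpActivations <- function(fit, x) {
  fw <- .mlpForward(fit$net, x, fit$task)
  L <- length(fit$net$W)
  list(input = fw$A[[1L]],
       hidden = if (L >= 2L) fw$A[2:L] else list(),  # post-ReLU hidden layers
       output = fw$A[[L + 1L]][, 1L])
}
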