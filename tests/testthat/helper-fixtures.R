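# Shared fixtures, all generated in code.

# small patient-only training problem on the adjusted scale
makeTrainingSet <- function(n = 120, noise = 0.1, seed = 42) {
  cfg <- syntheticConfig(nPsychosis = n, nHc = max(20, n %/% 4),
                         labelNoise = noise, seed = seed)
  co <- adjustProtocol(generateCohort(cfg))
  ot <- outcomeTable(co)
  pat <- ot$group == "psychosis"
  list(cohort = co, outcomes = ot,
       x = featureMatrix(co, "roi4", "patients"),
       y = as.logical(ot$improver[pat]),
       delta = ot$delta_bprs[pat])
}

# activation table straight from 0/1 matrices
makeTable <- function(xPlus, xMinus) {
  m <- ncol(xPlus)
  new("ActivationTable", xPlus = xPlus, xMinus = xMinus,
      neurons = S4Vectors::DataFrame(id = sprintf("h1:%d", seq_len(m)),
                                     layer = "h1", feature = NA_character_,
                                     unit = seq_len(m), threshold = 0,
                                     direction = ">"))
}

randomTable <- function(nNeurons, nPlus, nMinus, density = NULL) {
  if (is.null(density)) density <- runif(1, 0.15, 0.6)
  makeTable(
    matrix(as.numeric(runif(nPlus * nNeurons) < density), nPlus, nNeurons),
    matrix(as.numeric(runif(nMinus * nNeurons) < density), nMinus, nNeurons))
}

# hand-built deep model with fixed weights (4 inputs, one hidden layer)
makeFixedMlp <- function(W1, b1, w2, b2) {
  net <- list(W = list(W1, matrix(w2, ncol = 1)), b = list(b1, b2))
  fit <- list(mlp = list(net = net, sizes = c(nrow(W1), ncol(W1), 1L),
                         task = "binary", finalLoss = NA_real_,
                         epochsRun = 0L),
              yMean = 0, ySd = 1)
  new("TrainedModel",
      spec = classifierSpec("deep", "binary"),
      fit = fit, featureNames = paste0("f", seq_len(nrow(W1))))
}
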