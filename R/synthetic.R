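#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: four frontoparietal ROI activation betas per subject, a
#' protocol-version additive shift removable by residualization, raw BPRS
#' totals at baseline and one-year follow-up consistent with Improver labels,
#' and a planted single-feature threshold rule (`planted_feature >
#' planted_threshold` implies Improver) that rule-recovery tests can check
#' against.
#'
#' Class-conditional feature distributions are Gaussian; the class-specific
#' spreads default to values backed out of published 95% confidence intervals
#' of group mean adjusted betas at the published group sizes (82 patients,
#' 138 controls), which gives sd ~1.109 (patients) and ~0.989 (controls).
#' Because the Improver rate is a free parameter, the location of the two
#' side-truncated class components is calibrated by root-finding so that the
#' patient mixture mean equals the configured group mean.
#'
#' @param nPsychosis,nHc cohort sizes (defaults 82 and 138).
#' @param improverRate proportion of patients labelled Improver (default
#'   0.573).
#' @param plantedFeature feature carrying the planted rule (default
#'   `"L_DLPFC"`).
#' @param plantedThreshold decision threshold in adjusted-beta units
#'   (default 0.017).
#' @param thresholdMargin half-width of the sampling gap around the
#'   threshold, in beta units; keeps planted labels unambiguous (default
#'   0.05).
#' @param labelNoise proportion of patients whose label is flipped relative
#'   to the planted rule, in `[0, 0.5)`.
#' @param groupMeans numeric matrix `2 x 4` (rows `HC`, `psychosis`; columns
#'   the four ROIs) of group mean betas.
#' @param featureSd named numeric, per-group Gaussian sd of features.
#' @param protocolShift additive beta-unit shift applied to the raw features
#'   of AX-1 subjects (default 0.5).
#' @param protocolSplit proportion of subjects assigned protocol AX-1.
#' @param voxelwise also generate within-ROI voxel features.
#' @param nVoxelFeatures total voxel feature count, divisible by 4
#'   (default 252, i.e. 63 voxels per ROI).
#' @param voxelCorr pairwise correlation of within-ROI voxel noise.
#' @param voxelNoiseSd sd of voxel noise around the ROI beta.
#' @param bprsBaselineRange raw baseline BPRS interval, within `[29, 120]`.
#' @param bprsBaselineMean,bprsBaselineSd location/spread of the (clamped)
#'   Gaussian baseline draw; defaults 42.7 and 9.7.
#' @param seed integer; fully determines the cohort.
#' @return a `SyntheticConfig` object.
#' @seealso [generateCohort()]
#' @export
syntheticConfig <- function(nPsychosis = 82L, nHc = 138L,
                            improverRate = 0.573,
                            plantedFeature = "L_DLPFC",
                            plantedThreshold = 0.017,
                            thresholdMargin = 0.05,
                            labelNoise = 0,
                            groupMeans = NULL,
                            featureSd = c(HC = 0.165 * sqrt(138) / qnorm(0.975),
                                          psychosis = 0.24 * sqrt(82) / qnorm(0.975)),
                            protocolShift = 0.5,
                            protocolSplit = 0.5,
                            voxelwise = FALSE,
                            nVoxelFeatures = 252L,
                            voxelCorr = 0.3,
                            voxelNoiseSd = 0.5,
                            bprsBaselineRange = c(29, 120),
                            bprsBaselineMean = 42.7,
                            bprsBaselineSd = 9.7,
                            seed = 1L) {
  if (is.null(groupMeans)) {
    groupMeans <- rbind(HC = c(0.15, 0.12, 0.10, 0.10),
                        psychosis = c(-0.13, -0.10, -0.08, -0.08))
    colnames(groupMeans) <- .ROI_FEATURES
  }
  .assertScalarNumber(improverRate, "improverRate")
  if (improverRate <= 0 || improverRate >= 1)
    stop("improverRate must lie strictly in (0, 1)", call. = FALSE)
  .assertScalarNumber(labelNoise, "labelNoise", 0, 0.5 - 1e-12)
  .assertScalarNumber(protocolSplit, "protocolSplit", 0, 1)
  .assertScalarNumber(voxelCorr, "voxelCorr", 0, 1 - 1e-12)
  .assertScalarNumber(thresholdMargin, "thresholdMargin", 0)
  if (nPsychosis < 4L)
    stop("nPsychosis too small to realize both outcome classes", call. = FALSE)
  if (voxelwise && nVoxelFeatures %% 4L != 0L)
    stop("nVoxelFeatures must be divisible by 4 (one block per ROI)",
         call. = FALSE)
  if (bprsBaselineRange[1] < 29 || bprsBaselineRange[2] > 120 ||
      diff(bprsBaselineRange) < 0)
    stop("bprsBaselineRange must be an interval within [29, 120]", call. = FALSE)
  if (!plantedFeature %in% colnames(groupMeans))
    stop("plantedFeature must appear in groupMeans", call. = FALSE)
  structure(list(nPsychosis = as.integer(nPsychosis), nHc = as.integer(nHc),
                 improverRate = improverRate, plantedFeature = plantedFeature,
                 plantedThreshold = plantedThreshold,
                 thresholdMargin = thresholdMargin, labelNoise = labelNoise,
                 groupMeans = groupMeans, featureSd = featureSd,
                 protocolShift = protocolShift, protocolSplit = protocolSplit,
                 voxelwise = voxelwise,
                 nVoxelFeatures = as.integer(nVoxelFeatures),
                 voxelCorr = voxelCorr, voxelNoiseSd = voxelNoiseSd,
                 bprsBaselineRange = bprsBaselineRange,
                 bprsBaselineMean = bprsBaselineMean,
                 bprsBaselineSd = bprsBaselineSd,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# expectation of a one-sided truncated normal
.truncMeanUpper <- function(mu, sd, a) {
  alpha <- (a - mu) / sd
  mu + sd * exp(dnorm(alpha, log = TRUE) - pnorm(alpha, lower.tail = FALSE,
                                                 log.p = TRUE))
}
.truncMeanLower <- function(mu, sd, b) {
  beta <- (b - mu) / sd
  mu - sd * exp(dnorm(beta, log = TRUE) - pnorm(beta, log.p = TRUE))
}

# location mu0 such that the (rate, 1-rate) mixture of side-truncated
# N(mu0, sd) components has the requested mean
.calibrateLocation <- function(targetMean, sd, rate, lowerCut, upperCut) {
  g <- function(mu0)
    rate * .truncMeanUpper(mu0, sd, upperCut) +
      (1 - rate) * .truncMeanLower(mu0, sd, lowerCut) - targetMean
  span <- 10 * sd + abs(targetMean) + abs(upperCut) + 1
  mu0 <- uniroot(g, lower = targetMean - span, upper = targetMean + span,
                 extendInt = "upX", tol = 1e-10)$root
  pUp <- pnorm(upperCut, mu0, sd, lower.tail = FALSE)
  pLo <- pnorm(lowerCut, mu0, sd)
  if (pUp < 1e-6 || pLo < 1e-6)
    stop("improverRate is incompatible with the planted threshold margin: ",
         "a truncated class component has vanishing mass", call. = FALSE)
  mu0
}

.sampleTruncated <- function(n, mu, sd, cut, upper = TRUE) {
  if (n == 0L) return(numeric(0))
  if (upper) {
    p0 <- pnorm(cut, mu, sd)
    qnorm(p0 + runif(n) * (1 - p0), mu, sd)
  } else {
    p0 <- pnorm(cut, mu, sd)
    qnorm(runif(n) * p0, mu, sd)
  }
}

#' Generate a seeded synthetic cohort with a planted threshold rule
#'
#' Patients' planted-feature values are drawn from class-conditional
#' truncated Gaussians that straddle the planted threshold, so the pre-noise
#' Improver class equals `planted_feature > threshold` exactly; follow-up
#' BPRS totals are constructed so that percent-decrease labelling on the
#' rescaled scale (see [labelImprover()]) reproduces the assigned
#' (post-noise) label with zero mismatches. AX-1 subjects have
#' `protocolShift` added to every raw feature. Healthy controls carry
#' features (a reference distribution) but no follow-up BPRS.
#'
#' @param config a [syntheticConfig()] object.
#' @return a [PsychosisCohort-class]; `metadata()` carries the config, the
#'   planted rule and a per-subject ground-truth table (pre-noise class and
#'   noise-flip indicator), retrievable via [groundTruth()] and
#'   [plantedRule()].
#' @export
#' @examples
#' cohort <- generateCohort(syntheticConfig(nPsychosis = 40, nHc = 30, seed = 7))
#' table(colData(cohort)$group)
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(deriveSeed(config$seed, "cohort"), .generateCohortImpl(config))
}

.generateCohortImpl <- function(config) {
  nP <- config$nPsychosis; nH <- config$nHc
  feats <- colnames(config$groupMeans)
  pf <- config$plantedFeature
  t0 <- config$plantedThreshold; m <- config$thresholdMargin
  sdP <- config$featureSd[["psychosis"]]; sdH <- config$featureSd[["HC"]]

  trueClass <- runif(nP) < config$improverRate
  mu0 <- .calibrateLocation(config$groupMeans["psychosis", pf], sdP,
                            config$improverRate, t0 - m, t0 + m)
  planted <- numeric(nP)
  planted[trueClass] <- .sampleTruncated(sum(trueClass), mu0, sdP, t0 + m, TRUE)
  planted[!trueClass] <- .sampleTruncated(sum(!trueClass), mu0, sdP, t0 - m, FALSE)

  # other ROIs carry group-level means but no outcome signal
  betasP <- sapply(feats, function(f) {
    if (f == pf) planted
    else rnorm(nP, config$groupMeans["psychosis", f], sdP)
  })
  betasH <- sapply(feats, function(f) rnorm(nH, config$groupMeans["HC", f], sdH))

  flip <- runif(nP) < config$labelNoise
  label <- xor(trueClass, flip)

  # baseline raw BPRS; clamped Gaussian at the published cohort location
  rng <- config$bprsBaselineRange
  baseP <- pmin(pmax(round(rnorm(nP, config$bprsBaselineMean,
                                 config$bprsBaselineSd)), rng[1]), rng[2])
  bResc <- baseP - 24
  dec <- ifelse(label, runif(nP, 0.25 + 1e-9, 0.80), runif(nP, 0, 0.20 - 1e-9))
  fResc <- ifelse(label, floor(bResc * (1 - dec)), ceiling(bResc * (1 - dec)))
  followP <- fResc + 24

  protocol <- ifelse(runif(nP + nH) < config$protocolSplit, "AX-1", "AX-2")
  betas <- rbind(betasP, betasH)
  betas <- betas + config$protocolShift * (protocol == "AX-1")
  rownames(betas) <- NULL

  diagP <- sample(c("SZ", "BD"), nP, replace = TRUE, prob = c(65, 17) / 82)
  ids <- sprintf("S%04d", seq_len(nP + nH))
  cd <- DataFrame(subject_id = ids,
                  group = c(rep("psychosis", nP), rep("HC", nH)),
                  diagnosis = c(diagP, rep("HC", nH)),
                  protocol = protocol,
                  bprs_baseline_raw = c(baseP, rep(NA_real_, nH)),
                  bprs_followup_raw = c(followP, rep(NA_real_, nH)),
                  row.names = ids)
  rd <- DataFrame(feature = feats, roi = feats, kind = "roi",
                  row.names = feats)
  truth <- DataFrame(subject_id = ids[seq_len(nP)], trueClass = trueClass,
                     noiseFlip = flip, label = label,
                     row.names = ids[seq_len(nP)])
  se <- SummarizedExperiment(
    assays = SimpleList(betas = t(betas)),
    rowData = rd, colData = cd,
    metadata = list(config = config,
                    plantedRule = list(feature = pf, threshold = t0,
                                       direction = ">"),
                    groundTruth = truth))
  cohort <- new("PsychosisCohort", se)
  if (config$voxelwise) cohort <- generateVoxelwise(cohort, config)
  cohort
}

#' Add within-ROI voxelwise features to a cohort
#'
#' Each subject gains `nVoxelFeatures` voxel values partitioned equally
#' across the four ROIs. A voxel is its ROI beta plus equicorrelated
#' Gaussian noise: for subject i, ROI block k, voxel j,
#' `v = beta + sd * (sqrt(rho) * z_ik + sqrt(1 - rho) * e_ijk)`, so the
#' pairwise correlation of the noise of two voxels in the same block is
#' `rho = voxelCorr`. With `voxelNoiseSd = 0` every voxel equals its ROI
#' beta exactly.
#'
#' @param cohort a [PsychosisCohort-class] with the four ROI beta rows.
#' @param config a [syntheticConfig()] with `voxelwise` settings.
#' @return the cohort with voxel rows (`v001`, `v002`, ...) appended.
#' @export
generateVoxelwise <- function(cohort, config) {
  stopifnot(is(cohort, "PsychosisCohort"), inherits(config, "SyntheticConfig"))
  betas <- assay(cohort, "betas")
  miss <- setdiff(.ROI_FEATURES, rownames(betas))
  if (length(miss))
    stop("cohort lacks ROI beta rows: ", paste(miss, collapse = ", "),
         call. = FALSE)
  withSeed(deriveSeed(config$seed, "voxels"), {
    nV <- config$nVoxelFeatures
    per <- nV %/% 4L
    n <- ncol(betas)
    rho <- config$voxelCorr; sdv <- config$voxelNoiseSd
    vox <- matrix(0, nrow = nV, ncol = n)
    for (k in seq_along(.ROI_FEATURES)) {
      base <- betas[.ROI_FEATURES[k], ]
      shared <- rnorm(n)                      # one block factor per subject
      idio <- matrix(rnorm(per * n), per, n)
      block <- matrix(base, per, n, byrow = TRUE) +
        sdv * (sqrt(rho) * matrix(shared, per, n, byrow = TRUE) +
                 sqrt(1 - rho) * idio)
      vox[(k - 1L) * per + seq_len(per), ] <- block
    }
    vnames <- sprintf("v%03d", seq_len(nV))
    rownames(vox) <- vnames
    colnames(vox) <- colnames(betas)
    rdVox <- DataFrame(feature = vnames,
                       roi = rep(.ROI_FEATURES, each = per), kind = "voxel",
                       row.names = vnames)
    allAssay <- rbind(betas, vox)
    rd <- rbind(rowData(cohort)[rownames(betas), c("feature", "roi", "kind")],
                rdVox)
    se <- SummarizedExperiment(assays = SimpleList(betas = allAssay),
                               rowData = rd, colData = colData(cohort),
                               metadata = metadata(cohort))
    new("PsychosisCohort", se)
  })
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort a synthetic [PsychosisCohort-class].
#' @return `groundTruth()`: a [S4Vectors::DataFrame] with the pre-noise class,
#'   the noise-flip indicator and the assigned label per patient;
#'   `plantedRule()`: the planted rule as `list(feature, threshold, direction)`.
#' @export
groundTruth <- function(cohort) metadata(cohort)$groundTruth

#' @rdname groundTruth
#' @export
plantedRule <- function(cohort) metadata(cohort)$plantedRule
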