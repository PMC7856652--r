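#' Protocol-version adjustment of a single measure
#'
#' Regresses the measure on an MRI-protocol indicator by ordinary least
#' squares and returns the standardized residuals: raw residual divided by
#' the residual standard deviation on regression degrees of freedom
#' (`n - 2`). The output is mean-zero and exactly orthogonal to the protocol
#' indicator, which removes any additive between-protocol shift.
#'
#' @param values numeric measure, one value per subject.
#' @param protocol per-subject protocol labels with exactly two levels.
#' @return standardized residuals of the same length.
#' @export
#' @examples
#' adjustForProtocol(c(1, 3, 2, 4), c("AX-1", "AX-1", "AX-2", "AX-2"))
#' # -0.707  0.707 -0.707  0.707
adjustForProtocol <- function(values, protocol) {
  protocol <- as.factor(protocol)
  if (nlevels(droplevels(protocol)) != 2L)
    stop("exactly two protocol levels are required", call. = FALSE)
  if (any(table(protocol) < 2L))
    stop("each protocol level needs at least 2 subjects ",
         "(residual degrees of freedom)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite feature values", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, as.numeric(protocol) - 1), values)
  res <- fit$residuals
  s <- sqrt(sum(res^2) / (length(values) - 2L))
  if (s < .Machine$double.eps^0.5) {
    warning("zero residual variance; returning all-zero adjusted values")
    return(rep(0, length(values)))
  }
  res / s
}

#' Add protocol-adjusted features to a cohort
#'
#' Applies [adjustForProtocol()] independently to every feature row,
#' fitting on the pooled control + patient sample (adjusted values for both
#' groups then live on a common scale). The adjustment is fit once on the
#' full sample, not inside training folds; see the package vignette for the
#' leakage trade-off this mirrors.
#'
#' @param cohort a [PsychosisCohort-class].
#' @return the cohort with an `"adjusted"` assay appended.
#' @export
adjustProtocol <- function(cohort) {
  betas <- assay(cohort, "betas")
  prot <- colData(cohort)$protocol
  adj <- t(apply(betas, 1L, adjustForProtocol, protocol = prot))
  dimnames(adj) <- dimnames(betas)
  assay(cohort, "adjusted") <- adj
  cohort
}

#' Extract an analysis-ready subjects x features matrix
#'
#' @param cohort a [PsychosisCohort-class] (run [adjustProtocol()] first for
#'   `adjusted = TRUE`).
#' @param mode `"roi4"` for the four ROI mean-signal features in fixed order
#'   (`L_DLPFC`, `R_DLPFC`, `L_SPC`, `R_SPC`) or `"voxelwise"` for the voxel
#'   features.
#' @param subjects which subjects to keep: patients (the training sample),
#'   the healthy-control reference distribution, or all.
#' @param adjusted return protocol-adjusted values (default) or raw betas.
#' @return numeric matrix, subjects in rows, features in columns.
#' @export
featureMatrix <- function(cohort, mode = c("roi4", "voxelwise"),
                          subjects = c("patients", "hc", "all"),
                          adjusted = TRUE) {
  mode <- match.arg(mode)
  subjects <- match.arg(subjects)
  an <- if (adjusted) "adjusted" else "betas"
  if (!an %in% assayNames(cohort))
    stop("assay '", an, "' not present; run adjustProtocol() first",
         call. = FALSE)
  rows <- if (mode == "roi4") {
    miss <- setdiff(.ROI_FEATURES, rownames(cohort))
    if (length(miss))
      stop("missing ROI feature rows: ", paste(miss, collapse = ", "),
           call. = FALSE)
    .ROI_FEATURES
  } else {
    v <- rownames(cohort)[rowData(cohort)$kind == "voxel"]
    if (!length(v))
      stop("no voxel feature rows present; generate with voxelwise = TRUE",
           call. = FALSE)
    v
  }
  keep <- switch(subjects,
                 patients = colData(cohort)$group == "psychosis",
                 hc = colData(cohort)$group == "HC",
                 all = rep(TRUE, ncol(cohort)))
  t(assay(cohort, an)[rows, keep, drop = FALSE])
}
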