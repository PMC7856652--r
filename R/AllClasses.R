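#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assayNames colData rowData colData<-
NULL

.GROUP_LEVELS <- c("HC", "psychosis")
.DIAGNOSIS_LEVELS <- c("HC", "SZ", "BD")
.PROTOCOL_LEVELS <- c("AX-1", "AX-2")
.ROI_FEATURES <- c("L_DLPFC", "R_DLPFC", "L_SPC", "R_SPC")

#' Cohort container: ROI/voxel features x subjects
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' task-activation betas (rows = features, columns = subjects). The
#' `"betas"` assay holds measured values (protocol shift included for
#' synthetic cohorts); [adjustProtocol()] adds an `"adjusted"` assay of
#' standardized residuals. Clinical covariates (group, diagnosis, protocol
#' version, raw BPRS totals) live in `colData`; for synthetic cohorts the
#' generating configuration and ground truth live in `metadata`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("PsychosisCohort", contains = "SummarizedExperiment")

setValidity("PsychosisCohort", function(object) {
  cd <- colData(object)
  need <- c("subject_id", "group", "diagnosis", "protocol",
            "bprs_baseline_raw", "bprs_followup_raw")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("missing colData column(s): %s", paste(miss, collapse = ", ")))
  if (!all(cd$group %in% .GROUP_LEVELS))
    return("group must be one of HC/psychosis")
  if (!all(cd$protocol %in% .PROTOCOL_LEVELS))
    return("protocol must be one of AX-1/AX-2")
  if (anyDuplicated(cd$subject_id)) return("duplicate subject ids")
  b <- cd$bprs_baseline_raw
  if (any(!is.na(b) & b < 24))
    return("raw BPRS totals cannot fall below the 24-item scale minimum of 24")
  f <- cd$bprs_followup_raw
  if (any(!is.na(f) & f < 24))
    return("raw BPRS totals cannot fall below the 24-item scale minimum of 24")
  if (!"feature" %in% colnames(rowData(object)))
    return("rowData must carry a 'feature' column")
  TRUE
})

#' Specification of one learner
#'
#' @slot name classifier name; one of `"logistic"`, `"linear"`,
#'   `"naive_bayes"`, `"svm_poly"`, `"kstar"`, `"adaboost"`, `"j48"`,
#'   `"random_forest"`, `"deep"`, or one of the calibration baselines
#'   `"majority"`, `"coin"`, `"constant_mean"`.
#' @slot task `"binary"` or `"continuous"`.
#' @slot params name-specific hyperparameters.
#' @slot seed integer seed controlling any stochastic element of the fit.
#' @export
setClass("ClassifierSpec",
         representation(name = "character", task = "character",
                        params = "list", seed = "integer"))

#' A fitted learner with an opaque state
#'
#' For `"deep"` models the fitted state includes the full weight set, so
#' post-nonlinearity activations of every neuron can be recomputed for any
#' instance via [activations()].
#'
#' @slot spec the [ClassifierSpec-class] used for fitting.
#' @slot fit opaque fitted state.
#' @slot featureNames training feature layout; enforced at prediction.
#' @export
setClass("TrainedModel",
         representation(spec = "ClassifierSpec", fit = "list",
                        featureNames = "character"))

#' Repeated-holdout split plan
#'
#' @slot nRepetitions number of random train/test assortments.
#' @slot trainFraction fraction of subjects assigned to training.
#' @slot seed integer; fully determines the split sequence.
#' @slot stratified draw test sets stratified by class label.
#' @export
setClass("SplitPlan",
         representation(nRepetitions = "integer", trainFraction = "numeric",
                        seed = "integer", stratified = "logical"))

setValidity("SplitPlan", function(object) {
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie strictly between 0 and 1")
  if (object@nRepetitions < 1L) return("nRepetitions must be >= 1")
  TRUE
})

#' Binary neuron-activation tables split by class
#'
#' Rows are training instances, columns are network nodes (thresholded
#' input-feature indicator nodes followed by hidden units). Entry (i, j) is 1
#' iff instance i activated node j; rows are routed to `xPlus` (Improvers) or
#' `xMinus` (non-Improvers) by label.
#'
#' @slot xPlus,xMinus binary matrices with identical column layout.
#' @slot neurons a [S4Vectors::DataFrame] describing each column: layer
#'   (`"input"` or hidden layer index), source feature, threshold and
#'   direction for input indicator nodes.
#' @export
setClass("ActivationTable",
         representation(xPlus = "matrix", xMinus = "matrix",
                        neurons = "DataFrame"))

setValidity("ActivationTable", function(object) {
  if (ncol(object@xPlus) != ncol(object@xMinus))
    return("xPlus and xMinus must have identical column counts")
  if (nrow(object@neurons) != ncol(object@xPlus))
    return("neurons metadata must describe every column")
  vals <- c(object@xPlus, object@xMinus)
  if (length(vals) && !all(vals %in% c(0, 1)))
    return("activation entries must be 0/1")
  TRUE
})

#' DNF rule set extracted from a deep model
#'
#' @slot rules list of rules; each rule is a list with elements `class`
#'   (`"Improver"`/`"non-Improver"`), `literals` (list of
#'   `(feature, op, threshold)`), `accuracy` (training-label accuracy of the
#'   rule read as a two-sided classifier) and `agreement` (surrogate
#'   agreement with the originating node, for hidden-node rules).
#' @slot aPlus,aMinus selected node index sets (provenance).
#' @slot fidelity agreement of the pruned rule set with the deep model's own
#'   training predictions.
#' @slot coverage fraction of training instances matched by at least one rule.
#' @slot defaultClass class predicted when no rule fires.
#' @export
setClass("RuleSet",
         representation(rules = "list", aPlus = "integer", aMinus = "integer",
                        fidelity = "numeric", coverage = "numeric",
                        defaultClass = "character"))

setValidity("RuleSet", function(object) {
  if (length(intersect(object@aPlus, object@aMinus)))
    return("A+ and A- must be disjoint")
  if (length(object@fidelity) && (object@fidelity < 0 || object@fidelity > 1))
    return("fidelity must lie in [0, 1]")
  if (length(object@coverage) && (object@coverage < 0 || object@coverage > 1))
    return("coverage must lie in [0, 1]")
  TRUE
})

#' @rdname fitModel
#' @export
setGeneric("fitModel", function(spec, x, y, ...) standardGeneric("fitModel"))

#' @rdname predictModel
#' @export
setGeneric("predictModel", function(model, x, ...) standardGeneric("predictModel"))

#' @rdname activations
#' @export
setGeneric("activations", function(model, x, ...) standardGeneric("activations"))

setMethod("show", "ClassifierSpec", function(object) {
  cat(sprintf("ClassifierSpec '%s' (%s task), seed %d\n",
              object@name, object@task, object@seed))
  if (length(object@params)) {
    p <- vapply(object@params, function(v) paste(format(v), collapse = ","), "")
    cat("  params:", paste(names(p), p, sep = "=", collapse = "; "), "\n")
  }
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel '%s' (%s), %d feature(s)\n", object@spec@name,
              object@spec@task, length(object@featureNames)))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d repetitions of %.0f%%/%.0f%% train/test%s, seed %d\n",
              object@nRepetitions, 100 * object@trainFraction,
              100 * (1 - object@trainFraction),
              if (object@stratified) " (stratified)" else "", object@seed))
})

setMethod("show", "ActivationTable", function(object) {
  cat(sprintf("ActivationTable: %d Improver / %d non-Improver instances x %d nodes (%d input indicator, %d hidden)\n",
              nrow(object@xPlus), nrow(object@xMinus), ncol(object@xPlus),
              sum(object@neurons$layer == "input"),
              sum(object@neurons$layer != "input")))
})

setMethod("show", "RuleSet", function(object) {
  cat(sprintf("RuleSet: %d rule(s); fidelity %.3f, coverage %.3f\n",
              length(object@rules), object@fidelity, object@coverage))
  for (r in object@rules) {
    lits <- vapply(r$literals, function(l)
      sprintf("%s %s %.4g", l$feature, l$op, l$threshold), "")
    cat(sprintf("  IF %s THEN %s  [train acc %.3f]\n",
                paste(lits, collapse = " AND "), r$class, r$accuracy))
  }
  cat(sprintf("  OTHERWISE %s\n", object@defaultClass))
})

#' Accessors for rule sets
#' @param x a [RuleSet-class]
#' @return `rules()` the list of rules; `fidelity()`/`ruleCoverage()` scalars.
#' @export
rules <- function(x) x@rules

#' @rdname rules
#' @export
fidelity <- function(x) x@fidelity

#' @rdname rules
#' @export
ruleCoverage <- function(x) x@coverage

#' Bioconductor accessors re-exported for convenience
#' @importFrom SummarizedExperiment assayNames
#' @importFrom S4Vectors metadata
#' @name reexports
#' @aliases assay colData rowData assayNames metadata
#' @export assay
#' @export colData
#' @export rowData
#' @export assayNames
#' @export metadata
NULL
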