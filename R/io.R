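#' Write / read a cohort as tidy CSV
#'
#' One row per subject; columns `id`, `group`, `diagnosis`, `protocol`, the
#' ROI beta columns, optional voxel columns (`v001`...), and the raw BPRS
#' totals. Healthy-control rows legitimately lack follow-up (and baseline)
#' BPRS. Ground truth of synthetic cohorts travels separately as JSON
#' ([writeGroundTruth()]).
#'
#' @param cohort a [PsychosisCohort-class].
#' @param path CSV file path.
#' @return `writeCohort()` the path, invisibly; `readCohort()` a
#'   [PsychosisCohort-class].
#' @export
writeCohort <- function(cohort, path) {
  cd <- colData(cohort)
  betas <- t(assay(cohort, "betas"))
  df <- data.frame(id = cd$subject_id, group = cd$group,
                   diagnosis = cd$diagnosis, protocol = cd$protocol,
                   betas, check.names = FALSE,
                   bprs_baseline_raw = cd$bprs_baseline_raw,
                   bprs_followup_raw = cd$bprs_followup_raw)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "group", "diagnosis", "protocol", "bprs_baseline_raw",
            "bprs_followup_raw")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("cohort file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!df$group %in% .GROUP_LEVELS)
  if (length(bad))
    stop("invalid group value in data line ", bad[1], call. = FALSE)
  bad <- which(!df$protocol %in% .PROTOCOL_LEVELS)
  if (length(bad))
    stop("invalid protocol value in data line ", bad[1], call. = FALSE)
  featCols <- setdiff(colnames(df), need)
  for (fc in featCols) {
    v <- df[[fc]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(v))
      if (length(bad))
        stop("non-numeric value for feature '", fc, "' in data line ",
             bad[1], call. = FALSE)
      df[[fc]] <- vn
    }
  }
  betas <- t(as.matrix(df[featCols]))
  colnames(betas) <- df$id
  kind <- ifelse(grepl("^v[0-9]+$", featCols), "voxel", "roi")
  rd <- DataFrame(feature = featCols, roi = featCols, kind = kind,
                  row.names = featCols)
  cd <- DataFrame(subject_id = df$id, group = df$group,
                  diagnosis = df$diagnosis, protocol = df$protocol,
                  bprs_baseline_raw = df$bprs_baseline_raw,
                  bprs_followup_raw = df$bprs_followup_raw,
                  row.names = df$id)
  new("PsychosisCohort",
      SummarizedExperiment(assays = SimpleList(betas = betas),
                           rowData = rd, colData = cd))
}

#' Write / read synthetic ground truth as JSON
#'
#' @param cohort a synthetic [PsychosisCohort-class].
#' @param path JSON file path.
#' @return `readGroundTruth()`: list with `plantedRule` and a `truth`
#'   data.frame.
#' @export
writeGroundTruth <- function(cohort, path) {
  gt <- groundTruth(cohort)
  if (is.null(gt)) stop("cohort carries no ground truth", call. = FALSE)
  jsonlite::write_json(list(plantedRule = metadata(cohort)$plantedRule,
                            truth = as.data.frame(gt)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full analysis pipeline on a (synthetic) cohort
#'
#' Chains cohort generation (optional), outcome construction, protocol
#' adjustment, the repeated-holdout comparison of the requested learners,
#' pooling and McNemar comparisons against the deep learner, and rule
#' extraction from a deep model fit on all included patients. When
#' `outDir` is given, writes the cohort, outcomes, summaries (CSV/JSON), a
#' Markdown report and a reproducibility log recording every seed and
#' option in effect.
#'
#' @param config a [syntheticConfig()]; ignored when `cohort` is supplied.
#' @param cohort an existing [PsychosisCohort-class] (optional).
#' @param plan a [splitPlan()] (default 100 repetitions of 90/10).
#' @param classifiers names of binary-task learners to compare.
#' @param classifierParams named list of per-classifier hyperparameter
#'   lists, e.g. `list(deep = list(epochs = 200))`.
#' @param continuous also run the continuous-outcome comparison.
#' @param xai extract DNF rules from the deep model.
#' @param outDir output directory (created); `NULL` skips writing.
#' @param seed global seed; stage seeds are derived from it.
#' @return a result bundle (list), invisibly when writing.
#' @export
runPipeline <- function(config = syntheticConfig(), cohort = NULL,
                        plan = splitPlan(nRepetitions = 100L),
                        classifiers = c("logistic", shallowLearners(), "deep"),
                        classifierParams = list(), continuous = FALSE,
                        xai = TRUE, outDir = NULL, seed = 1L) {
  if (is.null(cohort)) {
    config$seed <- deriveSeed(seed, "synth")
    cohort <- generateCohort(config)
  }
  cohort <- adjustProtocol(cohort)
  outcomes <- outcomeTable(cohort)
  xAll <- featureMatrix(cohort, "roi4", subjects = "patients")
  inc <- outcomes$included[outcomes$group == "psychosis"]
  x <- xAll[inc, , drop = FALSE]
  yBin <- outcomes$improver[outcomes$group == "psychosis"][inc]
  plan@seed <- deriveSeed(seed, "splits")
  specsBin <- lapply(classifiers, function(nm)
    classifierSpec(if (nm == "linear") "logistic" else nm, "binary",
                   params = classifierParams[[nm]] %||% list(),
                   seed = deriveSeed(seed, nm)))
  ledger <- runHarness(specsBin, x, yBin, plan)
  sumBin <- summarizeBinary(ledger)
  pooled <- poolShallow(ledger)
  mcn <- NULL
  if ("deep" %in% classifiers) {
    others <- setdiff(unique(ledger$classifier), "deep")
    mcn <- do.call(rbind, lapply(others, function(nm) {
      m <- mcnemarVsDeep(ledger, nm)
      data.frame(method = nm, b = m$b, c = m$c, p = m$p)
    }))
  }
  contRes <- NULL
  if (continuous) {
    yCont <- outcomes$delta_bprs[outcomes$group == "psychosis"][inc]
    contNames <- union("linear", setdiff(classifiers, "logistic"))
    specsCont <- lapply(contNames, function(nm)
      classifierSpec(nm, "continuous",
                     params = classifierParams[[nm]] %||% list(),
                     seed = deriveSeed(seed, paste0("cont-", nm))))
    ledCont <- runHarness(specsCont, x, yCont, plan)
    contRes <- list(ledger = ledCont,
                    summary = summarizeContinuous(ledCont),
                    pooled = poolShallow(ledCont))
  }
  ruleRes <- NULL
  if (xai && "deep" %in% classifiers) {
    deepSpec <- classifierSpec("deep", "binary",
                               params = classifierParams[["deep"]] %||% list(),
                               seed = deriveSeed(seed, "xai"))
    model <- fitModel(deepSpec, x, yBin)
    tab <- binarizeActivations(model, x, yBin)
    cover <- solveSetCover(tab)
    rs <- extractRules(cover, tab, model, x, yBin)
    ctx <- ruleContextReport(rs, featureMatrix(cohort, "roi4", "hc"), x)
    ruleRes <- list(rules = rs, cover = cover, context = ctx)
  }
  bundle <- list(cohort = cohort, outcomes = outcomes, ledger = ledger,
                 summaryBinary = sumBin, pooled = pooled, mcnemar = mcn,
                 continuous = contRes, xai = ruleRes, seed = seed)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCohort(cohort, file.path(outDir, "cohort.csv"))
    if (!is.null(groundTruth(cohort)))
      writeGroundTruth(cohort, file.path(outDir, "truth.json"))
    utils::write.csv(as.data.frame(outcomes),
                     file.path(outDir, "outcomes.csv"), row.names = FALSE)
    utils::write.csv(rbind(sumBin, pooled),
                     file.path(outDir, "summary_binary.csv"),
                     row.names = FALSE)
    if (!is.null(mcn))
      utils::write.csv(mcn, file.path(outDir, "mcnemar.csv"),
                       row.names = FALSE)
    if (!is.null(contRes))
      utils::write.csv(rbind(contRes$summary,
                             cbind(contRes$pooled, pctDiffFromDeep = NA,
                                   pctDiffLo = NA, pctDiffHi = NA)),
                       file.path(outDir, "summary_continuous.csv"),
                       row.names = FALSE)
    if (!is.null(ruleRes)) {
      jsonlite::write_json(
        list(rules = lapply(ruleRes$rules@rules, function(r)
               list(class = r$class, accuracy = r$accuracy,
                    literals = r$literals)),
             fidelity = ruleRes$rules@fidelity,
             coverage = ruleRes$rules@coverage,
             defaultClass = ruleRes$rules@defaultClass),
        file.path(outDir, "rules.json"), auto_unbox = TRUE, digits = NA)
    }
    log <- list(globalSeed = seed,
                configHash = deriveSeed(0L, paste(deparse(config),
                                                  collapse = "")),
                plan = list(nRepetitions = plan@nRepetitions,
                            trainFraction = plan@trainFraction,
                            seed = plan@seed, stratified = plan@stratified),
                classifiers = classifiers,
                timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
    .writeReport(bundle, file.path(outDir, "report.md"), log$configHash)
    return(invisible(bundle))
  }
  bundle
}

.writeReport <- function(bundle, path, configHash) {
  fmtPct <- function(m, lo, hi) sprintf("%.1f%% (%.1f-%.1f%%)",
                                        100 * m, 100 * lo, 100 * hi)
  lines <- c(sprintf("# Prognosis model comparison (seed %s, config hash %s)",
                     bundle$seed, configHash), "",
             "## Binary outcome: mean accuracy over repetitions", "",
             "| method | accuracy (95% CI) | Improvers | non-Improvers |",
             "|---|---|---|---|")
  sb <- rbind(bundle$summaryBinary, bundle$pooled)
  for (i in seq_len(nrow(sb)))
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", sb$classifier[i],
                              fmtPct(sb$accuracy[i], sb$accuracyLo[i],
                                     sb$accuracyHi[i]),
                              fmtPct(sb$improverAccuracy[i],
                                     sb$improverAccuracyLo[i],
                                     sb$improverAccuracyHi[i]),
                              fmtPct(sb$nonImproverAccuracy[i],
                                     sb$nonImproverAccuracyLo[i],
                                     sb$nonImproverAccuracyHi[i])))
  if (!is.null(bundle$mcnemar)) {
    lines <- c(lines, "", "## McNemar tests vs the deep learner", "",
               "| method | b | c | exact p |", "|---|---|---|---|")
    m <- bundle$mcnemar
    for (i in seq_len(nrow(m)))
      lines <- c(lines, sprintf("| %s | %d | %d | %.4f |", m$method[i],
                                m$b[i], m$c[i], m$p[i]))
  }
  if (!is.null(bundle$continuous)) {
    lines <- c(lines, "", "## Continuous outcome: RMSE over repetitions", "",
               "| method | RMSE (95% CI) |", "|---|---|")
    sc <- bundle$continuous$summary
    for (i in seq_len(nrow(sc)))
      lines <- c(lines, sprintf("| %s | %.2f (%.2f-%.2f) |",
                                sc$classifier[i], sc$rmse[i], sc$rmseLo[i],
                                sc$rmseHi[i]))
  }
  if (!is.null(bundle$xai)) {
    lines <- c(lines, "", "## Extracted rules", "",
               utils::capture.output(show(bundle$xai$rules)))
  }
  writeLines(lines, path)
  invisible(path)
}
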