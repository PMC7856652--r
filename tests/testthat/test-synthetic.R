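test_that("the generator is fully seed-determined", {
  cfg <- syntheticConfig(nPsychosis = 40, nHc = 25, labelNoise = 0.1, seed = 7)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(assay(a, "betas"), assay(b, "betas"))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  expect_identical(as.data.frame(groundTruth(a)), as.data.frame(groundTruth(b)))
  cfg2 <- syntheticConfig(nPsychosis = 40, nHc = 25, labelNoise = 0.1, seed = 8)
  expect_false(identical(assay(a, "betas"),
                         assay(generateCohort(cfg2), "betas")))
})

test_that("without label noise the label equals the planted rule exactly", {
  cfg <- syntheticConfig(nPsychosis = 150, nHc = 30, labelNoise = 0, seed = 13)
  co <- generateCohort(cfg)
  gt <- groundTruth(co)
  pr <- plantedRule(co)
  pat <- colData(co)$group == "psychosis"
  planted <- assay(co, "betas")[pr$feature, pat] -
    cfg$protocolShift * (colData(co)$protocol[pat] == "AX-1")
  expect_identical(unname(as.logical(gt$label)), unname(planted > pr$threshold))
  expect_identical(as.logical(gt$label), as.logical(gt$trueClass))
})

test_that("generated BPRS trajectories reproduce the assigned labels with zero mismatches", {
  for (s in c(3, 17)) {
    cfg <- syntheticConfig(nPsychosis = 120, nHc = 20, labelNoise = 0.15,
                           seed = s)
    co <- generateCohort(cfg)
    ot <- outcomeTable(co)
    pat <- ot$group == "psychosis"
    expect_true(all(ot$included[pat]))
    expect_identical(unname(as.logical(ot$improver[pat])),
                     unname(as.logical(groundTruth(co)$label)))
  }
})

test_that("patient mean of the planted adjusted feature matches the configured group mean", {
  cfg <- syntheticConfig(nPsychosis = 10000L, nHc = 10L, protocolShift = 0,
                         seed = 21)
  co <- generateCohort(cfg)
  pat <- colData(co)$group == "psychosis"
  expect_lt(abs(mean(assay(co, "betas")["L_DLPFC", pat]) - (-0.13)), 0.02)
})

test_that("the noise-flip fraction stays within binomial 99% bounds of labelNoise", {
  cfg <- syntheticConfig(nPsychosis = 2000L, nHc = 10L, labelNoise = 0.1,
                         seed = 31)
  flips <- sum(groundTruth(generateCohort(cfg))$noiseFlip)
  expect_gte(flips, qbinom(0.005, 2000, 0.1))
  expect_lte(flips, qbinom(0.995, 2000, 0.1))
})

test_that("cohort invariants hold: baseline floor, HC reference structure", {
  co <- generateCohort(syntheticConfig(nPsychosis = 60, nHc = 40, seed = 2))
  cd <- colData(co)
  pat <- cd$group == "psychosis"
  expect_true(all(cd$bprs_baseline_raw[pat] >= 29))
  expect_true(all(cd$bprs_followup_raw[pat] >= 24))
  expect_true(all(is.na(cd$bprs_followup_raw[!pat])))
  expect_true(all(cd$diagnosis[pat] %in% c("SZ", "BD")))
})

test_that("degenerate configurations are rejected with a message", {
  expect_error(syntheticConfig(improverRate = 1), "strictly in")
  expect_error(syntheticConfig(nPsychosis = 2), "too small")
  expect_error(syntheticConfig(voxelwise = TRUE, nVoxelFeatures = 250L),
               "divisible by 4")
  # a margin so wide the truncated components lose all mass
  expect_error(generateCohort(syntheticConfig(thresholdMargin = 30, seed = 1)),
               "incompatible")
})

test_that("voxel blocks average to their ROI beta and split 63 per ROI at 252", {
  cfg <- syntheticConfig(nPsychosis = 15, nHc = 10, voxelwise = TRUE,
                         nVoxelFeatures = 252L, voxelNoiseSd = 0, seed = 4)
  co <- generateCohort(cfg)
  rd <- rowData(co)
  expect_equal(as.integer(table(rd$roi[rd$kind == "voxel"])), rep(63L, 4))
  betas <- assay(co, "betas")
  for (roi in c("L_DLPFC", "R_DLPFC", "L_SPC", "R_SPC")) {
    vox <- betas[rd$kind == "voxel" & rd$roi == roi, , drop = FALSE]
    # degenerate noise: every voxel equals its ROI beta
    expect_lt(max(abs(sweep(vox, 2, betas[roi, ]))), 1e-9)
  }
})

test_that("within-ROI voxel noise attains the configured pairwise correlation", {
  cfg <- syntheticConfig(nPsychosis = 5000L, nHc = 10L, voxelwise = TRUE,
                         nVoxelFeatures = 8L, voxelCorr = 0.5,
                         voxelNoiseSd = 0.5, seed = 6)
  co <- generateCohort(cfg)
  rd <- rowData(co)
  betas <- assay(co, "betas")
  cors <- c()
  for (roi in c("L_DLPFC", "R_DLPFC", "L_SPC", "R_SPC")) {
    vox <- betas[rd$kind == "voxel" & rd$roi == roi, , drop = FALSE]
    noise <- sweep(vox, 2, betas[roi, ])        # subtract the ROI beta
    cors <- c(cors, cor(noise[1, ], noise[2, ]))
  }
  expect_lt(max(abs(cors - 0.5)), 0.05)
})

test_that("voxel generation requires the ROI rows", {
  co <- generateCohort(syntheticConfig(nPsychosis = 20, nHc = 10, seed = 1))
  co2 <- co[c("L_DLPFC", "R_DLPFC"), ]
  expect_error(
    generateVoxelwise(new("PsychosisCohort", co2),
                      syntheticConfig(nPsychosis = 20, nHc = 10,
                                      voxelwise = TRUE, seed = 1)),
    "lacks ROI")
})
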