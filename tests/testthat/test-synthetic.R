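smallConfig <- function(seed = 1L, ...) {
  simulationConfig(nGenes = 60L, nTssExcluded = 10L, seed = seed, ...)
}

test_that("the generator is fully reproducible from its seed", {
  cfg <- smallConfig(seed = 9L)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(d1@counts, "counts"),
                   SummarizedExperiment::assay(d2@counts, "counts"))
  expect_identical(SummarizedExperiment::assay(d1@tpm, "tpm"),
                   SummarizedExperiment::assay(d2@tpm, "tpm"))
  expect_identical(variantRecords(d1@variants), variantRecords(d2@variants))
  expect_identical(panelGenes(d1@panel), panelGenes(d2@panel))
  d3 <- simulateDataset(smallConfig(seed = 10L))
  expect_false(identical(SummarizedExperiment::assay(d1@counts, "counts"),
                         SummarizedExperiment::assay(d3@counts, "counts")))
})

test_that("generated containers satisfy their class invariants", {
  ds <- simulateDataset(smallConfig(seed = 2L))
  expect_true(validObject(ds@panel))
  expect_true(validObject(ds@counts))
  expect_true(validObject(ds@tpm))
  expect_true(validObject(ds@variants))
})

test_that("the realized active fraction tracks the configured one", {
  cfg <- simulationConfig(nGenes = 2000L, nTssExcluded = 100L, seed = 3L)
  expr <- simulateExpression(cfg)
  gm <- expr$truth$groupMeanLog
  frac <- mean(pmin(gm[, 1], gm[, 2]) > 0.2)  # active irrespective of DE
  expect_lt(abs(frac - cfg@activeFraction), 0.03)
  expect_equal(sum(expr$truth$activity), round(cfg@activeFraction * 2000))
})

test_that("degenerate expression settings behave as advertised", {
  all_active <- simulateExpression(smallConfig(activeFraction = 1))
  expect_true(all(all_active$truth$activity))

  noiseless <- simulateExpression(smallConfig(replicateSd = 0))
  tpm <- SummarizedExperiment::assay(noiseless$tpm, "tpm")
  expect_equal(tpm[, 1], tpm[, 2])  # replicates within a group identical
  expect_equal(tpm[, 4], tpm[, 5])
})

test_that("expected chip counts scale with k, expression and library size", {
  cfg <- smallConfig(chipBackground = 0, dispersion = Inf)
  panel <- simulatePanel(cfg)
  ids <- panelGenes(panel)$gene_id
  k <- coverageFactors(panel)

  # equal expression, no background, Poisson: counts proportional to k
  gm <- matrix(5, length(ids), 1, dimnames = list(ids, "x"))
  tot <- numeric(length(ids))
  for (s in 1:50) {
    sim <- simulateChipCounts(gm, panel, cfg, replicates = 1L,
                              librarySizes = 1e6, seed = 1000L + s)
    tot <- tot + SummarizedExperiment::assay(sim$counts, "counts")[, 1]
  }
  ratio <- (tot / 50) / (1e6 * k / sum(k))
  expect_true(all(abs(ratio - 1) < 0.05))

  # zero expression with zero background -> expected count exactly 0
  gm0 <- gm; gm0[1:5, 1] <- 0
  sim0 <- simulateChipCounts(gm0, panel, cfg, replicates = 1L,
                             librarySizes = 1e6)
  expect_true(all(sim0$mu[1:5, 1] == 0))
  expect_true(all(SummarizedExperiment::assay(sim0$counts,
                                              "counts")[1:5, 1] == 0))

  # expected totals equal the library size; doubling doubles them
  sim2 <- simulateChipCounts(gm, panel, cfg, replicates = 2L,
                             librarySizes = c(5e5, 1e6))
  expect_equal(unname(colSums(sim2$mu)), c(5e5, 1e6))
  expect_error(simulateChipCounts(gm, panel, cfg, replicates = 1L,
                                  librarySizes = 0), "zero library size")
})

test_that("plasma mixing interpolates between background and tumor", {
  cfg <- smallConfig(seed = 4L)
  panel <- simulatePanel(cfg)
  ids <- panelGenes(panel)$gene_id
  bg <- simulateBackgroundProfile(cfg)
  tumor <- matrix(stats::setNames(rep(8, length(ids)), ids),
                  dimnames = list(ids, "NSCLC"))

  pc <- stats::setNames("NSCLC", "P01")
  p0 <- simulatePlasma(bg, tumor, panel, cfg, tumorFraction = 0,
                       patientConditions = pc, nHealthy = 1L)
  # at tf = 0 the patient's rate profile equals the healthy one
  expect_equal(p0$mu[, 2] / sum(p0$mu[, 2]), p0$mu[, 1] / sum(p0$mu[, 1]),
               tolerance = 1e-12)

  p1 <- simulatePlasma(bg, tumor, panel, cfg, tumorFraction = 1,
                       patientConditions = pc, nHealthy = 1L)
  k <- coverageFactors(panel)
  w <- k * (cfg@enrichmentSlope * tumor[, 1] + cfg@chipBackground)
  expect_equal(p1$mu[, 2] / sum(p1$mu[, 2]), w / sum(w), tolerance = 1e-12)

  badTumor <- tumor[-1, , drop = FALSE]
  expect_error(simulatePlasma(bg, badTumor, panel, cfg,
                              patientConditions = pc), "mismatched profiles")
})

test_that("a tumor-only gene gains positive relative enrichment at tf = 0.3", {
  cfg <- smallConfig(tumorFraction = 0.3)
  panel <- simulatePanel(cfg)
  ids <- panelGenes(panel)$gene_id
  bg <- simulateBackgroundProfile(cfg)
  g <- includedGenes(panel)[1]
  bg[g] <- 0
  tumor <- matrix(stats::setNames(rep(0, length(ids)), ids),
                  dimnames = list(ids, "NSCLC"))
  tumor[g, 1] <- 50

  vals <- vapply(1:20, function(s) {
    cfgS <- smallConfig(seed = 2000L + s, tumorFraction = 0.3)
    sim <- simulatePlasma(bg, tumor, panel, cfgS,
                          patientConditions = stats::setNames("NSCLC", "P01"))
    bgp <- makeBackground(sim$counts, panel,
                          healthy = paste0("H", 1:cfgS@nHealthy))
    rel <- cfchipRelativeEnrichment(sim$counts, bgp, panel, samples = "P01")
    rel@values[g, 1]
  }, numeric(1))
  expect_gt(mean(vals), 0)
})

test_that("variant simulation respects bias direction and panel membership", {
  cfg <- smallConfig()
  panel <- simulatePanel(cfg)

  # zero bias: cfchip MAF unbiased around the input MAF
  spec0 <- data.frame(patient_id = "P01", gene_id = "TP53",
                      variant_label = "v1", input_maf = 0.2,
                      expression_bias = 0)
  cfMafs <- vapply(1:200, function(s) {
    v <- variantRecords(simulateVariants(
      smallConfig(variantSpec = spec0, variantDepth = 500L), panel,
      seed = 3000L + s))
    v$maf[v$compartment == "cfchip"]
  }, numeric(1))
  se <- sqrt(0.2 * 0.8 / 500) / sqrt(200)
  expect_lt(abs(mean(cfMafs) - 0.2), 4 * se)

  bad <- data.frame(patient_id = "P01", gene_id = "NOT_ON_PANEL",
                    variant_label = "v", input_maf = 0.1,
                    expression_bias = 0)
  expect_error(simulateVariants(smallConfig(variantSpec = bad), panel),
               "non-panel gene")
})

test_that("a +0.3 logit bias at depth 2000 is detected in most runs", {
  spec <- data.frame(patient_id = sprintf("P%02d", 1:9), gene_id = "TP53",
                     variant_label = sprintf("v%d", 1:9),
                     input_maf = rep(c(0.1, 0.2, 0.15), 3),
                     expression_bias = 0.3)
  hits <- vapply(1:100, function(s) {
    v <- simulateVariants(smallConfig(variantSpec = spec), panel = NULL,
                          seed = 4000L + s)
    pairedMafTest(pairVariants(v))@p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the default dataset mirrors the study design", {
  ds <- simulateDataset(simulationConfig(seed = 7L))
  expect_equal(length(ds@panel), 197L)
  expect_equal(length(includedGenes(ds@panel)), 161L)
  cd <- SummarizedExperiment::colData(ds@counts)
  expect_equal(sum(cd$condition == "healthy"), 4L)
  expect_equal(sum(cd$assay_type == "cfchip" & cd$condition == "NSCLC"), 8L)
  expect_equal(sum(cd$assay_type == "cfchip" & cd$condition == "SCLC"), 4L)
  expect_equal(sum(cd$assay_type == "chip"), 6L)
})

test_that("the analytic AUC expectation matches Monte Carlo resampling", {
  cfg <- smallConfig(seed = 8L)
  ds <- simulateDataset(cfg)
  inc <- includedGenes(ds@panel)
  lab <- ds@truth$activity[inc]
  mu <- ds@truth$chipMu[inc, "NSCLC_rep1"]
  k <- coverageFactors(ds@panel)[inc]
  ea <- expectedRocAuc(mu, k, lab, size = cfg@dispersion)
  set.seed(99)
  mc <- vapply(1:300, function(i) {
    n <- rnbinom(length(mu), mu = mu, size = cfg@dispersion)
    rocActiveGenes(n / k, lab)@auc
  }, numeric(1))
  expect_lt(abs(ea - mean(mc)), 4 * sd(mc) / sqrt(300))
})
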