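## Seedable synthetic-data generator. Emulates the statistical structure the
## analysis assumes: a targeted capture panel with TSS-window-excluded genes,
## log-normal expression for active genes, negative-binomial panel read counts
## whose expectation scales with expression and capture footprint, a sparse
## hematopoietic background profile mixed with tumor signal at a configurable
## tumor fraction for plasma samples, and allele-specific variant depths.

## Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
## RNG state is untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## A handful of well-known lung-cancer panel genes head the synthetic panel so
## variant fixtures can reference them; these indices are never TSS-excluded
## (excluding a mutation-carrying gene would make its enrichment unassessable).
.namedPanelGenes <- c("TP53", "EGFR", "KRAS", "MET", "ALK", "BRAF", "PIK3CA",
                      "STK11", "KEAP1", "RB1", "DPYD", "WBSCR17")

defaultVariantSpec <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:9),
    gene_id = "TP53",
    variant_label = sprintf("TP53-v%d", 1:9),
    input_maf = c(0.10, 0.15, 0.20, 0.12, 0.25, 0.08, 0.18, 0.22, 0.14),
    expression_bias = c(rep(0.3, 7), -0.2, -0.2),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' All tunable parameters of the synthetic-data generator, with defaults
#' emulating a 197-gene lung-cancer capture panel profiled in cell lines
#' (triplicates), 8 NSCLC and 4 SCLC patients and 4 healthy donors.
#'
#' @slot nGenes number of panel genes (197).
#' @slot nTssExcluded genes captured solely within the TSS window (36).
#' @slot seed master seed; all randomness derives from it.
#' @slot kRange coverage factor range in bp, drawn uniformly.
#' @slot exprMeanlog,exprSdlog log-normal parameters (natural-log scale) of
#'   the baseline mean TPM of active genes.
#' @slot inactiveLevel mean \eqn{\log_2(TPM+1)} of inactive genes (< 0.2).
#' @slot activeFraction fraction of genes transcriptionally active.
#' @slot replicateSd replicate noise sd on the \eqn{\log_2(TPM+1)} scale.
#' @slot deFraction fraction of active genes differentially expressed.
#' @slot deEffect log2 shift applied to DE genes in the up group.
#' @slot enrichmentSlope expected reads per captured base per TPM unit
#'   (relative weight).
#' @slot chipBackground nonspecific pulldown rate in TPM-equivalents per base.
#' @slot dispersion negative-binomial size; \code{Inf} switches to Poisson.
#' @slot librarySizeRange per-sample total reads for cell-line ChIP and
#'   patient plasma samples, drawn log-uniformly.
#' @slot healthyLibrarySizeRange total reads for healthy-donor plasma samples;
#'   healthy plasma carries far less cfDNA than cancer patients', so healthy
#'   libraries are smaller.
#' @slot backgroundHighFraction,backgroundHighTpmRange,backgroundLowTpm shape
#'   of the sparse hematopoietic expression profile (most panel genes low, a
#'   handful high).
#' @slot tumorFraction fraction of plasma chromatin of tumor origin.
#' @slot nHealthy,nNsclc,nSclc cohort sizes.
#' @slot replicatesPerLine cell-line replicates per condition.
#' @slot variantSpec data.frame(patient_id, gene_id, variant_label,
#'   input_maf, expression_bias): one somatic variant per row;
#'   \code{expression_bias} is the logit shift of the cfChIP-compartment MAF.
#' @slot variantDepth input-compartment sequencing depth at variant sites.
#' @export
setClass("SimulationConfig",
  slots = c(
    nGenes = "integer", nTssExcluded = "integer", seed = "integer",
    kRange = "numeric", exprMeanlog = "numeric", exprSdlog = "numeric",
    inactiveLevel = "numeric", activeFraction = "numeric",
    replicateSd = "numeric", deFraction = "numeric", deEffect = "numeric",
    enrichmentSlope = "numeric", chipBackground = "numeric",
    dispersion = "numeric", librarySizeRange = "numeric",
    healthyLibrarySizeRange = "numeric",
    backgroundHighFraction = "numeric", backgroundHighTpmRange = "numeric",
    backgroundLowTpm = "numeric", tumorFraction = "numeric",
    nHealthy = "integer", nNsclc = "integer", nSclc = "integer",
    replicatesPerLine = "integer", variantSpec = "data.frame",
    variantDepth = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@tumorFraction < 0 || object@tumorFraction > 1)
    return("tumorFraction must lie in [0, 1]")
  if (object@activeFraction <= 0 || object@activeFraction > 1)
    return("activeFraction must lie in (0, 1]")
  if (object@dispersion <= 0) return("dispersion must be > 0")
  if (object@nTssExcluded >= object@nGenes)
    return("nTssExcluded must be < nGenes")
  if (any(object@kRange <= 0) || diff(object@kRange) < 0)
    return("kRange must be positive and non-decreasing")
  if (any(object@librarySizeRange <= 0) || diff(object@librarySizeRange) < 0)
    return("librarySizeRange must be positive and non-decreasing")
  if (any(object@healthyLibrarySizeRange <= 0) ||
      diff(object@healthyLibrarySizeRange) < 0)
    return("healthyLibrarySizeRange must be positive and non-decreasing")
  if (object@replicateSd < 0) return("replicateSd must be >= 0")
  if (object@deFraction < 0 || object@deFraction > 1)
    return("deFraction must lie in [0, 1]")
  TRUE
})

#' Construct a SimulationConfig
#'
#' @param nGenes,nTssExcluded,seed,kRange,exprMeanlog,exprSdlog,inactiveLevel
#'   see the class documentation.
#' @param activeFraction,replicateSd,deFraction,deEffect,enrichmentSlope see
#'   the class documentation.
#' @param chipBackground,dispersion,librarySizeRange,healthyLibrarySizeRange
#'   see the class documentation.
#' @param backgroundHighFraction see the class documentation.
#' @param backgroundHighTpmRange,backgroundLowTpm,tumorFraction,nHealthy see
#'   the class documentation.
#' @param nNsclc,nSclc,replicatesPerLine,variantSpec,variantDepth see the
#'   class documentation.
#' @return a [SimulationConfig]
#' @export
simulationConfig <- function(nGenes = 197L, nTssExcluded = 36L, seed = 1L,
                             kRange = c(500, 5000), exprMeanlog = 1.5,
                             exprSdlog = 1.5, inactiveLevel = 0.05,
                             activeFraction = 150 / 197, replicateSd = 0.2,
                             deFraction = 0.2, deEffect = 2,
                             enrichmentSlope = 1, chipBackground = 2,
                             dispersion = 8,
                             librarySizeRange = c(5e5, 2e6),
                             healthyLibrarySizeRange = c(1.5e5, 5e5),
                             backgroundHighFraction = 0.1,
                             backgroundHighTpmRange = c(20, 100),
                             backgroundLowTpm = 0.1, tumorFraction = 0.2,
                             nHealthy = 4L, nNsclc = 8L, nSclc = 4L,
                             replicatesPerLine = 3L,
                             variantSpec = defaultVariantSpec(),
                             variantDepth = 2000L) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), nTssExcluded = as.integer(nTssExcluded),
      seed = as.integer(seed), kRange = kRange, exprMeanlog = exprMeanlog,
      exprSdlog = exprSdlog, inactiveLevel = inactiveLevel,
      activeFraction = activeFraction, replicateSd = replicateSd,
      deFraction = deFraction, deEffect = deEffect,
      enrichmentSlope = enrichmentSlope, chipBackground = chipBackground,
      dispersion = dispersion, librarySizeRange = librarySizeRange,
      healthyLibrarySizeRange = healthyLibrarySizeRange,
      backgroundHighFraction = backgroundHighFraction,
      backgroundHighTpmRange = backgroundHighTpmRange,
      backgroundLowTpm = backgroundLowTpm, tumorFraction = tumorFraction,
      nHealthy = as.integer(nHealthy), nNsclc = as.integer(nNsclc),
      nSclc = as.integer(nSclc),
      replicatesPerLine = as.integer(replicatesPerLine),
      variantSpec = variantSpec, variantDepth = as.integer(variantDepth))
}

syntheticGeneIds <- function(n) {
  ids <- sprintf("G%03d", seq_len(n))
  m <- min(n, length(.namedPanelGenes))
  ids[seq_len(m)] <- .namedPanelGenes[seq_len(m)]
  ids
}

#' Simulate a capture panel
#'
#' Genes on one synthetic chromosome with random strand, gene lengths of
#' 20-150 kb, one capture interval per gene of \code{kRange} width, and
#' \code{nTssExcluded} genes whose interval lies solely within the first 25
#' percent of the gene body from the TSS. The panel is assembled through
#' [buildPanel()], so all panel invariants are enforced.
#'
#' @param config a [SimulationConfig].
#' @param seed RNG seed; defaults to an offset of the config master seed.
#' @return a [GenePanel]
#' @export
simulatePanel <- function(config, seed = config@seed + 101L) {
  withSeed(seed, {
    n <- config@nGenes
    ids <- syntheticGeneIds(n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- sample(20000:150000, n, replace = TRUE)
    offset <- (seq_len(n) - 1) * 2e5 + 1e4
    tss <- ifelse(strand == "+", offset, offset + len - 1)
    k <- round(stats::runif(n, config@kRange[1], config@kRange[2]))

    # never exclude the named mutation-carrying genes at the panel head
    eligible <- setdiff(seq_len(n), seq_len(min(n, length(.namedPanelGenes))))
    excl <- sort(sample(eligible, config@nTssExcluded))

    win <- floor(0.25 * len)
    start <- integer(n)
    for (i in seq_len(n)) {
      if (i %in% excl) {
        k[i] <- min(k[i], win[i])
        start[i] <- if (strand[i] == "+") tss[i] else tss[i] - k[i] + 1
      } else {
        start[i] <- if (strand[i] == "+") tss[i] + win[i]
                    else tss[i] - win[i] - k[i] + 1
      }
    }
    bed <- data.frame(chrom = "chrS", start = start, end = start + k,
                      gene_id = ids, stringsAsFactors = FALSE)
    tab <- data.frame(gene_id = ids, chrom = "chrS", strand = strand,
                      tss = tss, gene_length = len, k = k,
                      stringsAsFactors = FALSE)
    buildPanel(tab, captureIntervals = bed, name = "synthetic-panel")
  })
}

#' Simulate a TPM expression matrix with ground truth
#'
#' Active genes draw their baseline group-mean TPM from a log-normal;
#' inactive genes sit at \code{inactiveLevel} on the \eqn{\log_2(TPM+1)}
#' scale. A configurable
#' fraction of active genes is differentially expressed: the up group's mean
#' is shifted by \code{deEffect} (half up in NSCLC, half in SCLC). Replicates
#' add Gaussian noise on the log scale (truncated at 0).
#'
#' @inheritParams simulatePanel
#' @return list with \code{tpm} (a [TpmMatrix] with groups \code{NSCLC} and
#'   \code{SCLC}) and \code{truth} (activity, deDirection, groupMeanLog,
#'   groupMeanTpm).
#' @export
simulateExpression <- function(config, seed = config@seed + 202L) {
  withSeed(seed, {
    n <- config@nGenes
    ids <- syntheticGeneIds(n)
    nActive <- round(config@activeFraction * n)
    activeIdx <- sort(sample(seq_len(n), nActive))
    activity <- seq_len(n) %in% activeIdx

    base <- rep(config@inactiveLevel, n)
    base[activeIdx] <- log2(stats::rlnorm(nActive, config@exprMeanlog,
                                          config@exprSdlog) + 1)

    deDirection <- rep("none", n)
    nDe <- round(config@deFraction * nActive)
    if (nDe > 0) {
      deIdx <- sample(activeIdx, nDe)
      nUpA <- ceiling(nDe / 2)
      deDirection[deIdx[seq_len(nUpA)]] <- "up_in_a"
      if (nDe > nUpA) deDirection[deIdx[(nUpA + 1):nDe]] <- "up_in_b"
    }
    meanA <- base + config@deEffect * (deDirection == "up_in_a")
    meanB <- base + config@deEffect * (deDirection == "up_in_b")
    gm <- cbind(NSCLC = meanA, SCLC = meanB)
    rownames(gm) <- ids

    reps <- config@replicatesPerLine
    lv <- cbind(
      matrix(pmax(0, meanA + stats::rnorm(n * reps, 0, config@replicateSd)),
             nrow = n),
      matrix(pmax(0, meanB + stats::rnorm(n * reps, 0, config@replicateSd)),
             nrow = n))
    tpmMat <- pmax(2^lv - 1, 0)
    rownames(tpmMat) <- ids
    colnames(tpmMat) <- c(paste0("NSCLC_rep", seq_len(reps)),
                          paste0("SCLC_rep", seq_len(reps)))
    tpm <- TpmMatrix(tpmMat, group = rep(c("NSCLC", "SCLC"), each = reps))

    list(tpm = tpm,
         truth = list(activity = stats::setNames(activity, ids),
                      deDirection = stats::setNames(deDirection, ids),
                      groupMeanLog = gm,
                      groupMeanTpm = pmax(2^gm - 1, 0)))
  })
}

## Expected per-gene read counts for one sample: weight proportional to
## k_i * (slope * TPM_i + chipBackground), scaled to the library size.
expectedCounts <- function(tpmVec, panel, config, librarySize) {
  if (librarySize <= 0) stop("zero library size")
  k <- coverageFactors(panel)
  if (!identical(names(k), names(tpmVec)))
    stop("expression profile does not match the panel")
  w <- k * (config@enrichmentSlope * tpmVec + config@chipBackground)
  if (sum(w) <= 0) stop("degenerate expected-count weights")
  librarySize * w / sum(w)
}

drawCounts <- function(mu, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = dispersion)
}

drawLibrarySizes <- function(nSamples, range) {
  round(exp(stats::runif(nSamples, log(range[1]), log(range[2]))))
}

#' Simulate ChIP panel counts for cell-line samples
#'
#' Per sample, the expected count of gene \eqn{i} is proportional to
#' \code{enrichmentSlope} times its (linear) TPM plus the nonspecific
#' \code{chipBackground} rate, times the coverage factor \eqn{k_i}, scaled to
#' the library size; counts are drawn negative-binomially with the configured
#' dispersion (Poisson when \code{dispersion = Inf}).
#'
#' @param groupTpm genes x conditions matrix of linear group-mean TPM values
#'   (rownames = panel gene ids).
#' @param panel a [GenePanel].
#' @param config a [SimulationConfig].
#' @param replicates samples per condition.
#' @param librarySizes optional numeric vector (one per sample, recycled per
#'   condition x replicate in column order); drawn log-uniformly when NULL.
#' @param assayType stored sample assay type, default \code{"chip"}.
#' @param seed RNG seed.
#' @return list with \code{counts} (a [CfChipCounts]), \code{mu} (expected
#'   counts, genes x samples) and \code{librarySizes}.
#' @export
simulateChipCounts <- function(groupTpm, panel, config,
                               replicates = config@replicatesPerLine,
                               librarySizes = NULL, assayType = "chip",
                               seed = config@seed + 303L) {
  withSeed(seed, {
    groupTpm <- as.matrix(groupTpm)
    conds <- colnames(groupTpm)
    nS <- length(conds) * replicates
    if (is.null(librarySizes))
      librarySizes <- drawLibrarySizes(nS, config@librarySizeRange)
    if (any(librarySizes <= 0)) stop("zero library size")

    ids <- panelGenes(panel)$gene_id
    mu <- matrix(0, length(ids), nS, dimnames = list(ids, NULL))
    cnt <- mu
    nm <- character(nS)
    s <- 0L
    for (cond in conds) {
      tpmVec <- stats::setNames(groupTpm[ids, cond], ids)
      for (r in seq_len(replicates)) {
        s <- s + 1L
        nm[s] <- paste0(cond, "_rep", r)
        mu[, s] <- expectedCounts(tpmVec, panel, config, librarySizes[s])
        cnt[, s] <- drawCounts(mu[, s], config@dispersion)
      }
    }
    colnames(mu) <- colnames(cnt) <- nm
    counts <- CfChipCounts(cnt, condition = rep(conds, each = replicates),
                           assayType = assayType)
    list(counts = counts, mu = mu,
         librarySizes = stats::setNames(librarySizes, nm))
  })
}

#' Simulate a sparse hematopoietic expression profile
#'
#' Most panel genes are lowly expressed in blood cells; a small fraction is
#' high. This is the profile healthy-donor plasma cfChIP reflects.
#'
#' @inheritParams simulatePanel
#' @return named numeric vector of linear TPM values.
#' @export
simulateBackgroundProfile <- function(config, seed = config@seed + 606L) {
  withSeed(seed, {
    n <- config@nGenes
    ids <- syntheticGeneIds(n)
    tpm <- rep(config@backgroundLowTpm, n)
    nHigh <- round(config@backgroundHighFraction * n)
    if (nHigh > 0) {
      hi <- sample(seq_len(n), nHigh)
      tpm[hi] <- stats::runif(nHigh, config@backgroundHighTpmRange[1],
                              config@backgroundHighTpmRange[2])
    }
    stats::setNames(tpm, ids)
  })
}

#' Simulate plasma cfChIP counts (healthy donors and patients)
#'
#' Patient plasma chromatin is a mixture: expected counts follow
#' \code{(1 - tumorFraction) * background + tumorFraction * tumor} expression,
#' then negative-binomial sampling; healthy donors use tumor fraction 0.
#'
#' @param healthyTpm named numeric hematopoietic expression profile
#'   (linear TPM, panel gene ids).
#' @param tumorTpm genes x conditions matrix of tumor expression (linear TPM),
#'   one column per patient condition (e.g. NSCLC, SCLC).
#' @param panel a [GenePanel].
#' @param config a [SimulationConfig].
#' @param tumorFraction mixing fraction in [0, 1].
#' @param patientConditions named character vector: names are patient sample
#'   ids, values are columns of \code{tumorTpm}.
#' @param nHealthy number of healthy-donor samples.
#' @param seed RNG seed.
#' @return list with \code{counts} (a [CfChipCounts], healthy samples first),
#'   \code{mu} and \code{librarySizes}.
#' @export
simulatePlasma <- function(healthyTpm, tumorTpm, panel, config,
                           tumorFraction = config@tumorFraction,
                           patientConditions = NULL,
                           nHealthy = config@nHealthy,
                           seed = config@seed + 404L) {
  withSeed(seed, {
    tumorTpm <- as.matrix(tumorTpm)
    if (!identical(rownames(tumorTpm), names(healthyTpm)))
      stop("mismatched profiles: tumor and healthy gene sets differ")
    if (is.null(patientConditions)) {
      pid <- sprintf("P%02d", seq_len(config@nNsclc + config@nSclc))
      patientConditions <- stats::setNames(
        rep(c("NSCLC", "SCLC"), c(config@nNsclc, config@nSclc)), pid)
    }
    ids <- panelGenes(panel)$gene_id
    nS <- nHealthy + length(patientConditions)
    libs <- c(drawLibrarySizes(nHealthy, config@healthyLibrarySizeRange),
              drawLibrarySizes(length(patientConditions),
                               config@librarySizeRange))

    nm <- c(paste0("H", seq_len(nHealthy)), names(patientConditions))
    cond <- c(rep("healthy", nHealthy), unname(patientConditions))
    mu <- matrix(0, length(ids), nS, dimnames = list(ids, nm))
    cnt <- mu
    for (s in seq_len(nS)) {
      tf <- if (s <= nHealthy) 0 else tumorFraction
      mix <- (1 - tf) * healthyTpm[ids]
      if (tf > 0) mix <- mix + tf * tumorTpm[ids, patientConditions[[nm[s]]]]
      mu[, s] <- expectedCounts(stats::setNames(mix, ids), panel, config,
                                libs[s])
      cnt[, s] <- drawCounts(mu[, s], config@dispersion)
    }
    counts <- CfChipCounts(cnt, condition = cond, assayType = "cfchip")
    list(counts = counts, mu = mu,
         librarySizes = stats::setNames(libs, nm))
  })
}

#' Simulate allele-specific variant depths
#'
#' Input-compartment alt depths are binomial at the configured per-variant
#' MAF; the cfChIP compartment shifts the MAF on the logit scale by the
#' variant's \code{expression_bias}, emulating preferential pulldown of the
#' transcribed (mutant) allele. cfChIP depths are tied to the gene's read
#' count in the patient's cfChIP sample when counts are supplied.
#'
#' @param config a [SimulationConfig] (its \code{variantSpec} is used).
#' @param panel optional [GenePanel]; when supplied, variant genes must be on
#'   the panel.
#' @param counts optional [CfChipCounts] used to tie cfChIP depths to gene
#'   counts.
#' @param seed RNG seed.
#' @return a [VariantTable] with one input and one cfchip record per variant.
#' @export
simulateVariants <- function(config, panel = NULL, counts = NULL,
                             seed = config@seed + 505L) {
  withSeed(seed, {
    sp <- config@variantSpec
    if (!is.null(panel)) {
      off <- setdiff(sp$gene_id, panelGenes(panel)$gene_id)
      if (length(off))
        stop("variant on non-panel gene: ", paste(off, collapse = ", "))
    }
    cntMat <- if (!is.null(counts))
      SummarizedExperiment::assay(counts, "counts") else NULL

    rows <- lapply(seq_len(nrow(sp)), function(i) {
      v <- sp[i, ]
      dInput <- config@variantDepth
      dCf <- config@variantDepth
      if (!is.null(cntMat) && v$patient_id %in% colnames(cntMat) &&
          v$gene_id %in% rownames(cntMat))
        dCf <- max(50, round(cntMat[v$gene_id, v$patient_id]))
      mafCf <- stats::plogis(stats::qlogis(v$input_maf) + v$expression_bias)
      data.frame(
        patient_id = v$patient_id, gene_id = v$gene_id,
        variant_label = v$variant_label,
        compartment = c("input", "cfchip"),
        alt_depth = c(stats::rbinom(1, dInput, v$input_maf),
                      stats::rbinom(1, dCf, mafCf)),
        total_depth = c(dInput, dCf), stringsAsFactors = FALSE)
    })
    VariantTable(do.call(rbind, rows))
  })
}

## ---------------------------------------------------------------------------
## Full dataset
## ---------------------------------------------------------------------------

#' Complete synthetic dataset
#'
#' Bundles a simulated panel, TPM matrix, count matrix (cell-line ChIP plus
#' healthy and patient plasma cfChIP samples), variant table and the
#' generating ground truth.
#'
#' @slot panel,tpm,counts,variants the component containers.
#' @slot truth list: per-gene activity labels, true DE directions, group-mean
#'   expression, expected counts (\code{chipMu}, \code{plasmaMu}), library
#'   sizes and the background profile.
#' @slot config the generating [SimulationConfig].
#' @export
setClass("SyntheticDataset",
  slots = c(panel = "GenePanel", tpm = "TpmMatrix", counts = "CfChipCounts",
            variants = "VariantTable", truth = "list",
            config = "SimulationConfig")
)

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", length(object@panel), "genes,",
      ncol(object@counts), "count samples,",
      ncol(object@tpm), "TPM replicates,",
      nrow(variantRecords(object@variants)), "variant records (seed ",
      object@config@seed, ")\n")
})

#' Simulate a complete study
#'
#' Runs all generator stages with deterministic per-stage substreams derived
#' from the master seed: panel, expression (NSCLC and SCLC cell lines),
#' cell-line ChIP counts, hematopoietic background, healthy and patient
#' plasma cfChIP counts, and variant depths. Identical config (including
#' seed) yields byte-identical output.
#'
#' @param config a [SimulationConfig].
#' @return a [SyntheticDataset]
#' @export
simulateDataset <- function(config = simulationConfig()) {
  panel <- simulatePanel(config)
  expr <- simulateExpression(config)
  gm <- expr$truth$groupMeanTpm

  chip <- simulateChipCounts(gm, panel, config)
  bg <- simulateBackgroundProfile(config)
  plasma <- simulatePlasma(bg, gm, panel, config)
  variants <- simulateVariants(config, panel, counts = plasma$counts)

  allCounts <- cbind(SummarizedExperiment::assay(chip$counts, "counts"),
                     SummarizedExperiment::assay(plasma$counts, "counts"))
  cdChip <- SummarizedExperiment::colData(chip$counts)
  cdPlasma <- SummarizedExperiment::colData(plasma$counts)
  counts <- CfChipCounts(allCounts,
                         condition = c(cdChip$condition, cdPlasma$condition),
                         assayType = c(cdChip$assay_type,
                                       cdPlasma$assay_type))

  truth <- c(expr$truth,
             list(chipMu = chip$mu, plasmaMu = plasma$mu,
                  librarySizes = c(chip$librarySizes, plasma$librarySizes),
                  backgroundTpm = bg))

  new("SyntheticDataset", panel = panel, tpm = expr$tpm, counts = counts,
      variants = variants, truth = truth, config = config)
}

#' Write a synthetic dataset to TSV files
#'
#' Writes \code{panel.tsv}, \code{counts.tsv}, \code{samples.tsv},
#' \code{tpm.tsv}, \code{tpm_samples.tsv}, \code{variants.tsv} and
#' \code{truth.tsv} into a directory, in the interchange formats the pipeline
#' reads.
#'
#' @param dataset a [SyntheticDataset].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  writePanel(dataset@panel, file.path(dir, "panel.tsv"))

  cnt <- SummarizedExperiment::assay(dataset@counts, "counts")
  wt(data.frame(gene_id = rownames(cnt), cnt, check.names = FALSE),
     "counts.tsv")
  cd <- SummarizedExperiment::colData(dataset@counts)
  wt(data.frame(sample_id = rownames(cd), condition = cd$condition,
                assay_type = cd$assay_type), "samples.tsv")

  tpm <- SummarizedExperiment::assay(dataset@tpm, "tpm")
  wt(data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE), "tpm.tsv")
  wt(data.frame(sample_id = colnames(tpm),
                group = SummarizedExperiment::colData(dataset@tpm)$group),
     "tpm_samples.tsv")

  wt(variantRecords(dataset@variants), "variants.tsv")
  wt(data.frame(gene_id = names(dataset@truth$activity),
                active = unname(dataset@truth$activity),
                de_direction = unname(dataset@truth$deDirection)),
     "truth.tsv")
  invisible(dir)
}

## ---------------------------------------------------------------------------
## Analytic ROC expectation
## ---------------------------------------------------------------------------

#' Expected active-gene ROC AUC under the generative count model
#'
#' For a single sample with known expected counts \eqn{\mu_i}, coverage
#' factors \eqn{k_i} and activity labels, computes the expected AUC of the
#' enrichment-based classifier analytically: the probability, averaged over
#' all (active, inactive) gene pairs, that the active gene's scaled count
#' \eqn{N_i / k_i} exceeds the inactive gene's (ties weighted 1/2), by
#' numerically summing over the negative-binomial (or Poisson) probability
#' mass. Independent of any sampled counts.
#'
#' @param mu named numeric expected counts for one sample.
#' @param k coverage factors, same gene order.
#' @param labels logical activity labels, same gene order.
#' @param size negative-binomial size; \code{Inf} for Poisson.
#' @param maxPoints support points per inactive gene; larger supports are
#'   mass-binned (the tail function is smooth, so binning error is
#'   negligible).
#' @return expected AUC in [0, 1].
#' @export
expectedRocAuc <- function(mu, k, labels, size = Inf, maxPoints = 512L) {
  stopifnot(length(mu) == length(k), length(mu) == length(labels))
  act <- which(labels)
  inact <- which(!labels)
  if (!length(act) || !length(inact)) stop("both classes must be non-empty")

  dens <- function(y, m) {
    if (is.finite(size)) stats::dnbinom(y, mu = m, size = size)
    else stats::dpois(y, m)
  }
  upper <- function(fl, m) {
    if (is.finite(size)) stats::pnbinom(fl, mu = m, size = size,
                                        lower.tail = FALSE)
    else stats::ppois(fl, m, lower.tail = FALSE)
  }
  qmax <- function(m) {
    if (m == 0) return(0)
    if (is.finite(size)) stats::qnbinom(1e-9, mu = m, size = size,
                                        lower.tail = FALSE)
    else stats::qpois(1e-9, m, lower.tail = FALSE)
  }

  total <- 0
  for (j in inact) {
    ys <- 0:qmax(mu[j])
    pj <- dens(ys, mu[j])
    if (length(ys) > maxPoints) {
      grp <- ceiling(seq_along(ys) / ceiling(length(ys) / maxPoints))
      w <- as.numeric(tapply(pj, grp, sum))
      ys <- as.numeric(tapply(ys * pj, grp, sum)) / pmax(w, 1e-300)
      pj <- w
    }
    for (i in act) {
      t <- ys * k[i] / k[j]
      fl <- floor(t)
      pr <- upper(fl, mu[i]) + ifelse(t == fl, 0.5 * dens(fl, mu[i]), 0)
      total <- total + sum(pj * pr)
    }
  }
  total / (length(act) * length(inact))
}
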