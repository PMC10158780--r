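## End-to-end orchestration: input readers, validation, the staged pipeline
## (panel -> enrichment -> differential expression -> concordance -> MAF)
## and a plain-text run report. All interchange files are TSV.

#' Read pipeline input files
#'
#' \code{readCountMatrix}: TSV, first column \code{gene_id}, one column per
#' sample. \code{readSampleSheet}: TSV with \code{sample_id},
#' \code{condition}, \code{assay_type} (counts) or \code{sample_id},
#' \code{group} (TPM). \code{readTpmMatrix}: like the count matrix.
#'
#' @param path file path
#' @return matrix (gene ids as rownames) or data.frame for sheets.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname readCountMatrix
#' @export
readTpmMatrix <- readCountMatrix

#' @rdname readCountMatrix
#' @export
readSampleSheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble a pipeline configuration
#'
#' @param panel path to a panel table TSV ([readPanelTable()] format).
#' @param counts path to the count matrix TSV.
#' @param samples path to the count sample sheet TSV.
#' @param tpm path to the TPM matrix TSV.
#' @param tpmSamples path to the TPM sample sheet TSV.
#' @param variants optional path to a variant table TSV.
#' @param groupA,groupB condition/group labels contrasted throughout
#'   (expression groups, chip conditions and cfchip patient conditions share
#'   these labels).
#' @param healthyLabel condition labeling healthy cfChIP donors.
#' @param outDir output directory.
#' @param fcThreshold,qThreshold,activityThreshold,specificityCutoff,tssFraction,depthThreshold
#'   analysis thresholds (defaults 1, 0.05, 0.2, 0.75, 0.25, 100).
#' @param mafGene optional gene filter for the paired MAF test.
#' @param pseudo pseudo-enrichment for [relativeLog2FC()]; NULL = default rule.
#' @return a \code{list} of class \code{cfchipPipelineConfig}.
#' @export
pipelineConfig <- function(panel, counts, samples, tpm, tpmSamples,
                           variants = NULL, groupA, groupB,
                           healthyLabel = "healthy", outDir,
                           fcThreshold = 1, qThreshold = 0.05,
                           activityThreshold = 0.2, specificityCutoff = 0.75,
                           tssFraction = 0.25, depthThreshold = 100,
                           mafGene = NULL, pseudo = NULL) {
  stopifnot(fcThreshold > 0, qThreshold > 0, activityThreshold > 0,
            specificityCutoff >= 0, nchar(groupA) > 0, nchar(groupB) > 0,
            groupA != groupB)
  structure(list(
    panel = panel, counts = counts, samples = samples, tpm = tpm,
    tpmSamples = tpmSamples, variants = variants, groupA = groupA,
    groupB = groupB, healthyLabel = healthyLabel, outDir = outDir,
    fcThreshold = fcThreshold, qThreshold = qThreshold,
    activityThreshold = activityThreshold,
    specificityCutoff = specificityCutoff, tssFraction = tssFraction,
    depthThreshold = depthThreshold, mafGene = mafGene, pseudo = pseudo
  ), class = "cfchipPipelineConfig")
}

#' Validate pipeline inputs
#'
#' Checks file existence, gene-set alignment across files, count integrality
#' and sample-sheet consistency. Findings are returned, not thrown; the
#' \code{level} column separates \code{fatal} problems from \code{warning}s.
#'
#' @param config a [pipelineConfig()] list.
#' @return data.frame with columns \code{level} and \code{message}; zero rows
#'   when the inputs are clean.
#' @export
validateInputs <- function(config) {
  findings <- list()
  add <- function(level, msg)
    findings[[length(findings) + 1]] <<- data.frame(level = level,
                                                    message = msg)

  paths <- c(panel = config$panel, counts = config$counts,
             samples = config$samples, tpm = config$tpm,
             tpmSamples = config$tpmSamples)
  if (!is.null(config$variants)) paths <- c(paths, variants = config$variants)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) add("fatal", paste0("missing file: ",
                                                       paths[[nm]]))
  }
  if (any(vapply(findings, function(f) f$level == "fatal", logical(1))))
    return(do.call(rbind, findings))

  panelTab <- readPanelTable(config$panel)
  cnt <- readCountMatrix(config$counts)
  sheet <- readSampleSheet(config$samples)
  tpm <- readTpmMatrix(config$tpm)
  tpmSheet <- readSampleSheet(config$tpmSamples)

  extra <- setdiff(rownames(cnt), panelTab$gene_id)
  if (length(extra))
    add("fatal", paste0("count matrix gene(s) absent from panel: ",
                        paste(utils::head(extra, 5), collapse = ", ")))
  if (any(cnt != round(cnt)) || any(cnt < 0))
    add("fatal", "counts must be non-negative integers")
  if (!setequal(colnames(cnt), sheet$sample_id))
    add("fatal", "count columns and sample sheet disagree")
  if (!setequal(colnames(tpm), tpmSheet$sample_id))
    add("fatal", "TPM columns and TPM sample sheet disagree")
  extraT <- setdiff(rownames(tpm), panelTab$gene_id)
  if (length(extraT))
    add("warning", paste0("TPM gene(s) absent from panel: ",
                          paste(utils::head(extraT, 5), collapse = ", ")))
  for (g in c(config$groupA, config$groupB)) {
    n <- sum(tpmSheet$group == g)
    if (n == 0) add("fatal", paste0("no TPM replicates for group ", g))
    else if (n < 2)
      add("warning", paste0("group ", g, " has a single replicate; ",
                            "expression tests will be skipped"))
  }
  if (length(findings) == 0)
    return(data.frame(level = character(), message = character()))
  do.call(rbind, findings)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: rebuild/validate the panel; compute ChIP enrichment for cell-line
#' samples (with the \eqn{\sum E_i k_i = 10^9} conservation check); build the
#' healthy background and background-subtracted cfChIP enrichment when
#' healthy cfChIP samples are present (otherwise plain enrichment with a
#' report note); differential expression between the two groups; concordance
#' (rank correlation, per-group activity ROC, DE-vs-enrichment agreement);
#' paired MAF comparison when variants are supplied. Writes all stage outputs
#' as TSV plus a human-readable \code{report.txt}; output is a pure function
#' of the inputs.
#'
#' @param config a [pipelineConfig()] list.
#' @return invisibly, a list (\code{cfchipRunReport}) of per-stage summaries.
#' @export
runPipeline <- function(config) {
  findings <- validateInputs(config)
  if (any(findings$level == "fatal"))
    stop("input validation failed:\n  ",
         paste(findings$message[findings$level == "fatal"], collapse = "\n  "))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  ## stage: panel
  panel <- buildPanel(readPanelTable(config$panel),
                      tssFraction = config$tssFraction)
  writePanel(panel, file.path(config$outDir, "panel.tsv"))

  ## stage: enrichment
  cnt <- readCountMatrix(config$counts)
  sheet <- readSampleSheet(config$samples)
  sheet <- sheet[match(colnames(cnt), sheet$sample_id), ]
  counts <- CfChipCounts(cnt, condition = sheet$condition,
                         assayType = sheet$assay_type)
  cd <- SummarizedExperiment::colData(counts)

  chipSamples <- rownames(cd)[cd$assay_type == "chip"]
  chipProf <- NULL
  if (length(chipSamples)) {
    chipProf <- chipEnrichment(counts, panel, samples = chipSamples)
    writeEnrichment(chipProf, file.path(config$outDir, "enrichment_chip.tsv"))
  }

  healthy <- rownames(cd)[cd$condition == config$healthyLabel &
                          cd$assay_type == "cfchip"]
  cfSamples <- rownames(cd)[cd$assay_type == "cfchip" &
                            cd$condition != config$healthyLabel]
  cfProf <- NULL
  backgroundNote <- NULL
  if (length(cfSamples)) {
    if (length(healthy)) {
      bg <- makeBackground(counts, panel, healthy = healthy)
      cfProf <- cfchipRelativeEnrichment(counts, bg, panel,
                                         samples = cfSamples)
      writeTsv(data.frame(gene_id = bg@gene_id, mean_count = bg@meanCounts),
               file.path(config$outDir, "background.tsv"))
    } else {
      backgroundNote <- "no background subtraction (no healthy samples)"
      cfProf <- chipEnrichment(counts, panel, samples = cfSamples)
    }
    writeEnrichment(cfProf, file.path(config$outDir, "enrichment_cfchip.tsv"))
  }

  conservation <- vapply(
    Filter(Negate(is.null), list(chip = chipProf, cfchip = cfProf)),
    function(p) {
      k <- coverageFactors(panel)[p@gene_id]
      max(abs(colSums(p@values * k) / 1e9 - 1))
    }, numeric(1))

  ## stage: differential expression
  tpmMat <- readTpmMatrix(config$tpm)
  tpmSheet <- readSampleSheet(config$tpmSamples)
  tpmSheet <- tpmSheet[match(colnames(tpmMat), tpmSheet$sample_id), ]
  tpm <- TpmMatrix(tpmMat, group = tpmSheet$group)
  de <- differentialExpression(tpm, config$groupA, config$groupB,
                               fcThreshold = config$fcThreshold,
                               qThreshold = config$qThreshold,
                               activityThreshold = config$activityThreshold)
  writeTsv(de, file.path(config$outDir, "de.tsv"))

  ## stage: concordance
  act <- classifyActive(tpm, config$groupA, config$groupB,
                        config$activityThreshold)
  gm <- groupMeanLog(tpm, c(config$groupA, config$groupB))

  concProf <- if (!is.null(cfProf)) cfProf else chipProf
  concCd <- cd[concProf@sourceSamples, , drop = FALSE]
  sA <- rownames(concCd)[concCd$condition == config$groupA]
  sB <- rownames(concCd)[concCd$condition == config$groupB]
  agreement <- NULL
  relFc <- NULL
  if (length(sA) && length(sB)) {
    relFc <- relativeLog2FC(groupMeanEnrichment(concProf, sA),
                            groupMeanEnrichment(concProf, sB),
                            pseudo = config$pseudo)
    deCovered <- de[de$gene_id %in% names(relFc), ]
    agreement <- agreementAnalysis(deCovered, relFc)
    writeTsv(data.frame(gene_id = names(relFc), enrichment_log2fc = relFc),
             file.path(config$outDir, "enrichment_log2fc.tsv"))
  }

  rocs <- list()
  spearman <- list()
  if (!is.null(chipProf)) {
    chipCd <- cd[chipProf@sourceSamples, , drop = FALSE]
    for (g in c(config$groupA, config$groupB)) {
      gs <- rownames(chipCd)[chipCd$condition == g]
      if (!length(gs)) next
      scores <- groupMeanEnrichment(chipProf, gs)
      labels <- act[match(names(scores), act$gene_id),
                    if (g == config$groupA) "active_a" else "active_b"]
      if (length(unique(labels)) == 2) {
        roc <- rocActiveGenes(scores, labels)
        rocs[[g]] <- roc
        writeTsv(roc@curve, file.path(config$outDir,
                                      paste0("roc_", g, ".tsv")))
      }
      gmG <- gm[names(scores), g]
      if (stats::sd(gmG) > 0 && stats::sd(scores) > 0)
        spearman[[g]] <- spearmanCor(scores, gmG)
    }
  }

  ## stage: MAF
  maf <- NULL
  pairs <- NULL
  if (!is.null(config$variants)) {
    variants <- readVariantTable(config$variants)
    pairs <- pairVariants(variants)
    writeTsv(pairs, file.path(config$outDir, "maf_pairs.tsv"))
    if (nrow(pairs) >= 2) {
      maf <- pairedMafTest(pairs, gene = config$mafGene)
    }
  }

  report <- structure(list(
    n_genes = length(panel), n_included = length(includedGenes(panel)),
    n_tss_excluded = sum(panelGenes(panel)$tss_excluded),
    n_k_zero = sum(panelGenes(panel)$k == 0),
    n_chip_samples = length(chipSamples), n_cfchip_samples = length(cfSamples),
    n_healthy = length(healthy), background_note = backgroundNote,
    conservation_max_rel_err = conservation,
    n_genes_tested = sum(de$status != "filtered_inactive"),
    n_filtered_inactive = sum(de$status == "filtered_inactive"),
    n_up_in_a = sum(de$status == "up_in_a"),
    n_up_in_b = sum(de$status == "up_in_b"),
    agreement = agreement, rocs = rocs, spearman = spearman, maf = maf,
    n_maf_pairs = if (is.null(pairs)) 0L else nrow(pairs),
    config = config
  ), class = "cfchipRunReport")

  writeRunReport(report, file.path(config$outDir, "report.txt"))
  invisible(report)
}

writeRunReport <- function(report, path) {
  lines <- c(
    "cfChIPquant run report",
    sprintf("panel: %d genes, %d included, %d TSS-window excluded, %d with k=0",
            report$n_genes, report$n_included, report$n_tss_excluded,
            report$n_k_zero),
    sprintf("samples: %d chip, %d cfchip (patients), %d healthy donors",
            report$n_chip_samples, report$n_cfchip_samples, report$n_healthy))
  if (!is.null(report$background_note))
    lines <- c(lines, paste("note:", report$background_note))
  for (nm in names(report$conservation_max_rel_err))
    lines <- c(lines, sprintf(
      "conservation (sum E*k = 1e9, %s): max relative error %.3g", nm,
      report$conservation_max_rel_err[[nm]]))
  lines <- c(lines, sprintf(
    "differential expression: %d tested, %d filtered inactive, %d up in %s, %d up in %s",
    report$n_genes_tested, report$n_filtered_inactive, report$n_up_in_a,
    report$config$groupA, report$n_up_in_b, report$config$groupB))
  if (!is.null(report$agreement)) {
    s <- report$agreement@sensitivity
    lines <- c(lines, sprintf(
      "agreement: sensitivity %s = %s, %s = %s, Fisher p = %.4g",
      report$config$groupA, formatC(s[["up_in_a"]], digits = 3,
                                    format = "fg"),
      report$config$groupB, formatC(s[["up_in_b"]], digits = 3,
                                    format = "fg"),
      report$agreement@fisher_p))
  }
  for (g in names(report$rocs)) {
    r <- report$rocs[[g]]
    lines <- c(lines, sprintf(
      "roc (%s): AUC %.4f, SE %.4f, z %.3f, p %.3g, sens@spec%.2f %.3f",
      g, r@auc, r@se, r@z, r@p_value, report$config$specificityCutoff,
      sensitivityAtSpecificity(r, report$config$specificityCutoff)))
  }
  for (g in names(report$spearman)) {
    sp <- report$spearman[[g]]
    lines <- c(lines, sprintf(
      "spearman enrichment~expression (%s): rho %.4f, p %.3g", g, sp$rho,
      sp$p_value))
  }
  if (!is.null(report$maf)) {
    m <- report$maf
    lines <- c(lines, sprintf(
      "paired MAF (n=%d pairs): mean diff %.3f pp (95%% CI %.3f..%.3f), p %.4g, %d up / %d down",
      m@n_pairs, m@mean_difference, m@ci95[1], m@ci95[2], m@p_value,
      m@direction[["positive"]], m@direction[["negative"]]))
  } else {
    lines <- c(lines, sprintf("paired MAF: %d pairs (no test run)",
                              report$n_maf_pairs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.cfchipRunReport <- function(x, ...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeRunReport(x, tmp)
  cat(readLines(tmp), sep = "\n")
  invisible(x)
}
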