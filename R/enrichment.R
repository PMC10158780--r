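## Per-gene enrichment quantification on a targeted capture panel.
##
## For a (cf)ChIP sample with deduplicated read counts N_i over panel genes,
## enrichment of gene i is
##
##     E_i = N_i * 1e9 / (T * k_i),      T = sum over included genes of N_i
##
## an RPKM-like rate per captured base per sequenced read (the 1e9 scales to
## reads per billion * base). For plasma cfChIP samples the hematopoietic
## background is removed by subtracting the average healthy-donor counts:
##
##     E_i = (N_i - Hbar_i) * 1e9 / ((sum N - sum Hbar) * k_i)
##
## Both forms conserve sum(E_i * k_i) = 1e9 over included genes.

## genes x samples count matrix restricted to the panel's included genes,
## ordered like the panel.
includedCounts <- function(counts, panel) {
  m <- SummarizedExperiment::assay(counts, "counts")
  inc <- includedGenes(panel)
  if (length(inc) == 0L)
    stop("panel has no included genes; enrichment is undefined")
  missing <- setdiff(inc, rownames(m))
  if (length(missing))
    stop("count matrix lacks included panel gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  ks <- coverageFactors(panel)[inc]
  if (any(ks == 0)) stop("included gene with k = 0 (panel invariant breach)")
  m[inc, , drop = FALSE]
}

#' ChIP enrichment (coverage-factor normalized read rates)
#'
#' Computes per-gene enrichment \eqn{E_i = N_i \cdot 10^9 / (T \cdot k_i)}
#' for each selected sample, where \eqn{T} is the sample's total read count
#' over panel-included genes and \eqn{k_i} the gene's coverage factor.
#' Panel-excluded genes carry no value. Scaling all counts of a sample by a
#' positive constant leaves the result unchanged (sequencing-depth
#' invariance), and \eqn{\sum_i E_i k_i = 10^9} over included genes.
#'
#' @param counts a [CfChipCounts] (or any SummarizedExperiment with a
#'   \code{counts} assay and gene-id rownames).
#' @param panel a [GenePanel].
#' @param samples optional character vector of sample (column) names; default
#'   all columns.
#' @return an [EnrichmentProfile] with \code{kind = "chip"}.
#' @export
chipEnrichment <- function(counts, panel, samples = NULL) {
  m <- includedCounts(counts, panel)
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  total <- colSums(m)
  if (any(total == 0))
    stop("empty sample: ", paste(colnames(m)[total == 0], collapse = ", "))
  k <- coverageFactors(panel)[rownames(m)]
  vals <- sweep(m, 2, total, "/") * 1e9 / k
  new("EnrichmentProfile", gene_id = rownames(m), values = as.matrix(vals),
      kind = "chip", sourceSamples = colnames(m))
}

#' Healthy-donor background profile
#'
#' Averages per-gene cfChIP read counts over healthy donors, yielding the
#' hematopoietic background \eqn{\bar H_i} subtracted from patient samples in
#' [cfchipRelativeEnrichment()]. Restricted to panel-included genes.
#'
#' @param counts a [CfChipCounts].
#' @param panel a [GenePanel].
#' @param healthy character vector of healthy sample (column) names, or
#'   \code{NULL} to select columns with \code{condition == "healthy"} and
#'   \code{assay_type == "cfchip"}.
#' @return a [BackgroundProfile].
#' @export
makeBackground <- function(counts, panel, healthy = NULL) {
  if (is.null(healthy)) {
    cd <- SummarizedExperiment::colData(counts)
    healthy <- rownames(cd)[cd$condition == "healthy" &
                            cd$assay_type == "cfchip"]
  }
  if (length(healthy) == 0L) stop("no healthy samples")
  m <- includedCounts(counts, panel)[, healthy, drop = FALSE]
  h <- rowMeans(m)
  new("BackgroundProfile", gene_id = rownames(m), meanCounts = h,
      totalMean = sum(h), nDonors = length(healthy))
}

#' Background-subtracted cfChIP enrichment
#'
#' Patient plasma cfChIP counts contain signal from non-tumor (largely
#' hematopoietic) circulating chromatin. This subtracts the average
#' healthy-donor counts gene-wise before normalizing:
#' \eqn{E_i = (N_i - \bar H_i) \cdot 10^9 / ((\sum N - \sum \bar H) k_i)}.
#' Values can be negative (depletion below the healthy background). With an
#' all-zero background this reduces exactly to [chipEnrichment()].
#'
#' @inheritParams chipEnrichment
#' @param background a [BackgroundProfile] over the same panel.
#' @return an [EnrichmentProfile] with \code{kind = "cfchip_relative"}.
#' @export
cfchipRelativeEnrichment <- function(counts, background, panel,
                                     samples = NULL) {
  m <- includedCounts(counts, panel)
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  if (!identical(background@gene_id, rownames(m)))
    stop("background gene set does not match the panel's included genes")
  denomLib <- colSums(m) - background@totalMean
  if (any(abs(denomLib) < .Machine$double.eps * background@totalMean + 1e-12))
    stop("degenerate background-subtracted library size")
  k <- coverageFactors(panel)[rownames(m)]
  vals <- sweep(m - background@meanCounts, 2, denomLib, "/") * 1e9 / k
  new("EnrichmentProfile", gene_id = rownames(m), values = as.matrix(vals),
      kind = "cfchip_relative", sourceSamples = colnames(m))
}

#' Per-gene arithmetic mean enrichment over a profile's samples
#'
#' @param profile an [EnrichmentProfile]
#' @param samples optional subset of sample names
#' @return named numeric vector of per-gene mean enrichment
#' @export
groupMeanEnrichment <- function(profile, samples = NULL) {
  v <- profile@values
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  rowMeans(v)
}

#' Relative enrichment log2 fold change between groups
#'
#' \eqn{\log_2 FC_i = \log_2(\bar E_i^a + \epsilon) - \log_2(\bar E_i^b +
#' \epsilon)} on group-mean enrichment, with negative group means clamped to
#' zero before the log (background-subtracted enrichment can be negative). A
#' positive value indicates increased enrichment in group a. By default the
#' pseudo-enrichment \eqn{\epsilon} is half the smallest positive group-mean
#' value across both groups (fallback \code{1e-3}).
#'
#' @param groupA,groupB [EnrichmentProfile]s (their samples are averaged), or
#'   named numeric vectors of group-mean enrichment.
#' @param pseudo positive pseudo-enrichment; \code{NULL} for the default rule.
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
relativeLog2FC <- function(groupA, groupB, pseudo = NULL) {
  a <- if (methods::is(groupA, "EnrichmentProfile"))
    groupMeanEnrichment(groupA) else groupA
  b <- if (methods::is(groupB, "EnrichmentProfile"))
    groupMeanEnrichment(groupB) else groupB
  if (!identical(names(a), names(b)))
    stop("group enrichment profiles cover different gene sets")
  a <- pmax(a, 0)
  b <- pmax(b, 0)
  if (is.null(pseudo)) {
    pos <- c(a[a > 0], b[b > 0])
    pseudo <- if (length(pos)) min(pos) / 2 else 1e-3
  }
  if (pseudo <= 0) stop("pseudo must be > 0")
  log2(a + pseudo) - log2(b + pseudo)
}

#' Write / read enrichment profiles
#'
#' Tab-separated gene_id plus one column per sample; the profile kind is
#' recorded in a leading comment line.
#'
#' @param profile an [EnrichmentProfile]
#' @param path file path
#' @export
writeEnrichment <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind=", profile@kind), con)
  df <- data.frame(gene_id = profile@gene_id, profile@values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnrichment
#' @return \code{readEnrichment}: an [EnrichmentProfile]
#' @export
readEnrichment <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub("^# kind=", "", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  new("EnrichmentProfile", gene_id = df$gene_id, values = vals, kind = kind,
      sourceSamples = colnames(vals))
}
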