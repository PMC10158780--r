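#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
NULL

## ---------------------------------------------------------------------------
## GenePanel
## ---------------------------------------------------------------------------

#' Targeted capture gene panel
#'
#' A \code{GenePanel} holds the per-gene capture geometry and normalization
#' constants of a hybridization-capture panel: for every gene its transcription
#' start site, gene length, strand, the coverage factor \eqn{k_i} (number of
#' bases captured at depth above a reference threshold), whether the gene is
#' captured solely within the TSS-proximal window where H3K36me3 is depleted,
#' and whether it is included in enrichment computations.
#'
#' All coordinates are 0-based, half-open (BED convention). The \code{genes}
#' slot has columns \code{gene_id}, \code{chrom}, \code{strand}, \code{tss},
#' \code{gene_length}, \code{k}, \code{tss_excluded}, \code{included};
#' \code{intervals} is a \code{GRanges} of normalized (merged, non-overlapping)
#' capture intervals with a \code{gene_id} metadata column, possibly empty when
#' the panel was built from a precomputed \code{k} column alone.
#'
#' @slot genes data.frame of per-gene records (see Details).
#' @slot intervals \code{GRanges} of capture intervals, \code{gene_id} in mcols.
#' @slot name single character panel name.
#'
#' @seealso [buildPanel()], [computeCoverageFactor()], [flagTssExcluded()]
#' @export
setClass("GenePanel",
  slots = c(genes = "data.frame", intervals = "GRanges", name = "character")
)

setValidity("GenePanel", function(object) {
  g <- object@genes
  need <- c("gene_id", "chrom", "strand", "tss", "gene_length", "k",
            "tss_excluded", "included")
  if (!all(need %in% names(g)))
    return(paste("genes is missing columns:",
                 paste(setdiff(need, names(g)), collapse = ", ")))
  if (anyDuplicated(g$gene_id)) return("gene_ids must be unique")
  if (!all(g$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (any(g$gene_length <= 0)) return("gene_length must be > 0")
  if (any(g$k < 0) || any(g$k != round(g$k)))
    return("coverage factor k must be a non-negative integer base count")
  if (any(g$included & g$k == 0))
    return("genes with k = 0 cannot be included")
  if (length(object@name) != 1L) return("name must be a single string")
  TRUE
})

#' @describeIn GenePanel number of genes on the panel
#' @param x,object a \code{GenePanel}
#' @export
setMethod("length", "GenePanel", function(x) nrow(x@genes))

setMethod("show", "GenePanel", function(object) {
  g <- object@genes
  cat("GenePanel \"", object@name, "\": ", nrow(g), " genes, ",
      sum(g$included), " included (", sum(g$tss_excluded),
      " TSS-window excluded, ", sum(g$k == 0), " with k = 0)\n", sep = "")
})

#' Panel accessors
#'
#' \code{panelGenes} returns the per-gene table; \code{includedGenes} the ids of
#' genes entering enrichment sums; \code{coverageFactors} the named integer
#' vector of coverage factors \eqn{k_i}; \code{captureIntervals} the normalized
#' capture geometry.
#'
#' @param panel a \code{GenePanel}
#' @return see description
#' @export
panelGenes <- function(panel) panel@genes

#' @rdname panelGenes
#' @export
includedGenes <- function(panel) panel@genes$gene_id[panel@genes$included]

#' @rdname panelGenes
#' @export
coverageFactors <- function(panel) {
  stats::setNames(as.integer(panel@genes$k), panel@genes$gene_id)
}

#' @rdname panelGenes
#' @export
captureIntervals <- function(panel) panel@intervals

## ---------------------------------------------------------------------------
## Count and expression containers
## ---------------------------------------------------------------------------

#' Panel read counts for (cf)ChIP samples
#'
#' \code{CfChipCounts} extends \code{SummarizedExperiment}: one \code{counts}
#' assay of per-gene deduplicated read counts, with sample metadata columns
#' \code{condition} (e.g. \code{healthy}, \code{NSCLC}, \code{SCLC}, a cell
#' line) and \code{assay_type} (\code{chip}, \code{cfchip} or \code{input}).
#'
#' @export
setClass("CfChipCounts", contains = "SummarizedExperiment")

setValidity("CfChipCounts", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("a 'counts' assay is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(m != round(m))) return("counts must be integers")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "assay_type") %in% names(cd)))
    return("colData must have 'condition' and 'assay_type'")
  if (!all(cd$assay_type %in% c("chip", "cfchip", "input")))
    return("assay_type must be one of chip, cfchip, input")
  if (is.null(rownames(object))) return("gene_id rownames are required")
  TRUE
})

#' Construct a CfChipCounts object
#'
#' @param counts genes x samples matrix of non-negative integer read counts,
#'   rownames = gene ids.
#' @param condition character vector, one condition label per sample.
#' @param assayType character vector (or scalar) in \code{chip}, \code{cfchip},
#'   \code{input}.
#' @return a \code{CfChipCounts}
#' @export
CfChipCounts <- function(counts, condition, assayType) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (length(assayType) == 1L) assayType <- rep(assayType, ncol(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      condition = as.character(condition),
      assay_type = as.character(assayType),
      row.names = colnames(counts)
    )
  )
  new("CfChipCounts", se)
}

#' TPM expression matrix with replicate grouping
#'
#' \code{TpmMatrix} extends \code{SummarizedExperiment}: one \code{tpm} assay
#' (non-negative transcripts-per-million values) and a \code{group} column in
#' \code{colData} mapping replicates to groups.
#'
#' @export
setClass("TpmMatrix", contains = "SummarizedExperiment")

setValidity("TpmMatrix", function(object) {
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    return("a 'tpm' assay is required")
  if (any(SummarizedExperiment::assay(object, "tpm") < 0))
    return("TPM values must be non-negative")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    return("colData must have a 'group' column")
  if (is.null(rownames(object))) return("gene_id rownames are required")
  TRUE
})

#' Construct a TpmMatrix
#'
#' @param tpm genes x replicates matrix of TPM values, rownames = gene ids.
#' @param group character vector of group labels, one per replicate column.
#' @return a \code{TpmMatrix}
#' @export
TpmMatrix <- function(tpm, group) {
  tpm <- as.matrix(tpm)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(tpm))
  )
  new("TpmMatrix", se)
}

## ---------------------------------------------------------------------------
## Enrichment containers
## ---------------------------------------------------------------------------

#' Healthy-donor cfChIP background profile
#'
#' Per-gene arithmetic mean read counts over healthy-donor cfChIP samples
#' (\eqn{\bar H_i}), restricted to panel-included genes, together with the
#' total \eqn{\sum_i \bar H_i} used as the background library size.
#'
#' @slot gene_id character gene ids (panel-included genes, panel order).
#' @slot meanCounts named numeric mean counts.
#' @slot totalMean numeric sum of meanCounts.
#' @slot nDonors integer number of healthy samples averaged.
#' @export
setClass("BackgroundProfile",
  slots = c(gene_id = "character", meanCounts = "numeric",
            totalMean = "numeric", nDonors = "integer")
)

setValidity("BackgroundProfile", function(object) {
  if (length(object@meanCounts) != length(object@gene_id))
    return("meanCounts and gene_id lengths differ")
  if (any(object@meanCounts < 0)) return("mean counts must be non-negative")
  tol <- 1e-9 * max(1, abs(object@totalMean))
  if (abs(object@totalMean - sum(object@meanCounts)) > tol)
    return("totalMean must equal sum(meanCounts)")
  if (object@nDonors < 1L) return("at least one donor required")
  TRUE
})

setMethod("show", "BackgroundProfile", function(object) {
  cat("BackgroundProfile:", length(object@gene_id), "genes,",
      object@nDonors, "healthy donors, total mean counts",
      format(object@totalMean, digits = 6), "\n")
})

#' Per-gene enrichment values
#'
#' Enrichment of panel-included genes, one column per sample. For
#' \code{kind = "chip"} values are the library-size and footprint normalized
#' rates \eqn{N_i 10^9 / (T k_i)} and are non-negative; for
#' \code{kind = "cfchip_relative"} the healthy background has been subtracted
#' and values may be negative (depletion below the hematopoietic background).
#'
#' @slot gene_id character gene ids (panel-included genes).
#' @slot values numeric matrix genes x samples.
#' @slot kind \code{"chip"} or \code{"cfchip_relative"}.
#' @slot sourceSamples character provenance (sample ids).
#' @export
setClass("EnrichmentProfile",
  slots = c(gene_id = "character", values = "matrix", kind = "character",
            sourceSamples = "character")
)

setValidity("EnrichmentProfile", function(object) {
  if (nrow(object@values) != length(object@gene_id))
    return("values rows must match gene_id")
  if (!object@kind %in% c("chip", "cfchip_relative"))
    return("kind must be 'chip' or 'cfchip_relative'")
  if (object@kind == "chip" && any(object@values < 0, na.rm = TRUE))
    return("chip enrichment values must be non-negative")
  TRUE
})

setMethod("show", "EnrichmentProfile", function(object) {
  cat("EnrichmentProfile (", object@kind, "): ", length(object@gene_id),
      " genes x ", ncol(object@values), " sample(s)\n", sep = "")
})

#' Enrichment accessors
#'
#' @param profile an \code{EnrichmentProfile}
#' @return \code{enrichmentValues}: the genes x samples numeric matrix;
#'   \code{enrichmentKind}: the profile kind.
#' @export
enrichmentValues <- function(profile) profile@values

#' @rdname enrichmentValues
#' @export
enrichmentKind <- function(profile) profile@kind

## ---------------------------------------------------------------------------
## Variants
## ---------------------------------------------------------------------------

#' Somatic variant depths per patient and compartment
#'
#' Tabular container of per-variant read depths in the \code{input} (plasma
#' cfDNA before immunoprecipitation) and \code{cfchip} compartments. The
#' mutational allele fraction \code{maf = alt_depth / total_depth} is derived
#' on construction.
#'
#' @slot variants data.frame with columns \code{patient_id}, \code{gene_id},
#'   \code{variant_label}, \code{compartment}, \code{alt_depth},
#'   \code{total_depth}, \code{maf}.
#' @export
setClass("VariantTable", slots = c(variants = "data.frame"))

setValidity("VariantTable", function(object) {
  v <- object@variants
  need <- c("patient_id", "gene_id", "variant_label", "compartment",
            "alt_depth", "total_depth", "maf")
  if (!all(need %in% names(v)))
    return(paste("missing columns:", paste(setdiff(need, names(v)),
                                           collapse = ", ")))
  if (!all(v$compartment %in% c("input", "cfchip")))
    return("compartment must be 'input' or 'cfchip'")
  if (any(v$total_depth <= 0)) return("total_depth must be > 0")
  if (any(v$alt_depth < 0) || any(v$alt_depth > v$total_depth))
    return("alt_depth must lie in [0, total_depth]")
  if (any(abs(v$maf - v$alt_depth / v$total_depth) > 1e-12))
    return("maf must equal alt_depth / total_depth")
  TRUE
})

#' Construct a VariantTable
#'
#' @param variants data.frame with columns \code{patient_id}, \code{gene_id},
#'   \code{variant_label}, \code{compartment}, \code{alt_depth},
#'   \code{total_depth}. \code{maf} is computed.
#' @return a \code{VariantTable}
#' @export
VariantTable <- function(variants) {
  variants <- as.data.frame(variants)
  variants$maf <- variants$alt_depth / variants$total_depth
  new("VariantTable", variants = variants)
}

#' @rdname VariantTable
#' @param x a \code{VariantTable}
#' @return \code{variantRecords}: the underlying data.frame.
#' @export
variantRecords <- function(x) x@variants

setMethod("show", "VariantTable", function(object) {
  v <- object@variants
  cat("VariantTable:", nrow(v), "records,",
      length(unique(v$patient_id)), "patients,",
      length(unique(paste(v$patient_id, v$variant_label))), "variants\n")
})

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' ROC analysis result
#'
#' AUC via the Mann-Whitney identity (ties weighted 1/2), Hanley-McNeil
#' standard error, z-ratio \eqn{(AUC - 0.5)/SE} and its two-tailed normal
#' p-value, plus the full step curve over observed thresholds.
#'
#' @slot auc,se,z,p_value numeric scalars.
#' @slot curve data.frame with columns threshold, specificity, sensitivity.
#' @slot n_active,n_inactive integer class sizes.
#' @export
setClass("RocResult",
  slots = c(auc = "numeric", se = "numeric", z = "numeric",
            p_value = "numeric", curve = "data.frame",
            n_active = "integer", n_inactive = "integer")
)

setValidity("RocResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  if (object@se < 0) return("se must be non-negative")
  if (object@n_active < 1L || object@n_inactive < 1L)
    return("both classes must be non-empty")
  TRUE
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf(
    "RocResult: AUC = %.4f (SE %.4f), z = %.3f, p = %.3g  [%d active vs %d inactive]\n",
    object@auc, object@se, object@z, object@p_value,
    object@n_active, object@n_inactive))
})

#' Differential expression vs enrichment agreement
#'
#' @slot sensitivity named numeric, per-direction fraction of differentially
#'   expressed genes whose relative enrichment log2 fold change is concordant.
#' @slot contingency 2x2 integer table, rows = DE direction, columns =
#'   enrichment sign (positive / non-positive).
#' @slot fisher_p two-sided Fisher's exact p on the contingency table.
#' @slot geneLists list of gene id vectors per contingency cell.
#' @slot n_zero number of DE genes with exactly zero enrichment log2FC
#'   (counted as disagreement).
#' @export
setClass("AgreementResult",
  slots = c(sensitivity = "numeric", contingency = "matrix",
            fisher_p = "numeric", geneLists = "list", n_zero = "integer")
)

setValidity("AgreementResult", function(object) {
  if (!identical(dim(object@contingency), c(2L, 2L)))
    return("contingency must be 2x2")
  if (any(object@contingency < 0)) return("contingency must be non-negative")
  ok <- !is.na(object@sensitivity)
  if (any(object@sensitivity[ok] < 0 | object@sensitivity[ok] > 1))
    return("sensitivities must lie in [0, 1]")
  TRUE
})

setMethod("show", "AgreementResult", function(object) {
  cat("AgreementResult\n  sensitivity up_in_a:",
      format(object@sensitivity[["up_in_a"]], digits = 3),
      " up_in_b:", format(object@sensitivity[["up_in_b"]], digits = 3),
      "\n  Fisher's exact p =", format(object@fisher_p, digits = 4), "\n")
  print(object@contingency)
})

#' Paired input-vs-cfChIP allele fraction comparison
#'
#' @slot n_pairs number of (patient, variant) pairs tested.
#' @slot mean_difference mean of per-pair MAF differences, cfchip minus input,
#'   in percentage points.
#' @slot ci95 numeric length-2 t-based 95 percent confidence interval.
#' @slot p_value two-sided paired t-test p-value.
#' @slot direction named integer counts of pairs with positive / negative /
#'   zero difference.
#' @slot differences per-pair differences (percentage points).
#' @export
setClass("PairedMafResult",
  slots = c(n_pairs = "integer", mean_difference = "numeric",
            ci95 = "numeric", p_value = "numeric", direction = "integer",
            differences = "numeric")
)

setValidity("PairedMafResult", function(object) {
  if (abs(object@mean_difference - mean(object@differences)) > 1e-12)
    return("mean_difference must equal the mean of per-pair differences")
  if (length(object@ci95) != 2L) return("ci95 must have length 2")
  if (object@mean_difference < object@ci95[1] - 1e-12 ||
      object@mean_difference > object@ci95[2] + 1e-12)
    return("ci95 must bracket mean_difference")
  TRUE
})

setMethod("show", "PairedMafResult", function(object) {
  cat(sprintf(
    "PairedMafResult: n = %d, mean difference = %.2f%% (95%% CI %.2f-%.2f%%), p = %.4g\n",
    object@n_pairs, object@mean_difference, object@ci95[1], object@ci95[2],
    object@p_value))
  cat("  direction: ", object@direction[["positive"]], " up, ",
      object@direction[["negative"]], " down, ",
      object@direction[["zero"]], " unchanged\n", sep = "")
})
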