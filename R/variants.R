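## Mutational allele fractions and the paired input-vs-cfChIP comparison.
## A MAF shift between the plasma input and the H3K36me3-immunoprecipitated
## compartment reports allele-specific transcription of the mutant allele.

#' Mutational allele fraction
#'
#' @param altDepth non-negative integer alt-allele read depth.
#' @param totalDepth positive integer total read depth.
#' @return \code{altDepth / totalDepth} in [0, 1].
#' @export
computeMaf <- function(altDepth, totalDepth) {
  if (any(totalDepth <= 0)) stop("total_depth must be > 0")
  if (any(altDepth < 0) || any(altDepth > totalDepth))
    stop("alt_depth must lie in [0, total_depth]")
  altDepth / totalDepth
}

#' Pair variants across the input and cfChIP compartments
#'
#' Keeps one pair per (patient, variant) observed in \emph{both} compartments;
#' records present in only one compartment are dropped (their count is
#' reported in a message). Duplicate (patient, variant, compartment) records
#' are an error.
#'
#' @param variants a [VariantTable] or its underlying data.frame.
#' @return data.frame with one row per pair: \code{patient_id},
#'   \code{gene_id}, \code{variant_label}, \code{maf_input},
#'   \code{maf_cfchip}, \code{depth_input}, \code{depth_cfchip}.
#' @export
pairVariants <- function(variants) {
  v <- if (methods::is(variants, "VariantTable")) variantRecords(variants)
       else as.data.frame(variants)
  if ("maf" %in% names(v) == FALSE)
    v$maf <- computeMaf(v$alt_depth, v$total_depth)
  key <- paste(v$patient_id, v$variant_label, v$compartment, sep = "\r")
  if (anyDuplicated(key)) stop("ambiguous pairing: duplicate (patient, ",
                               "variant, compartment) record")
  inp <- v[v$compartment == "input", ]
  cfc <- v[v$compartment == "cfchip", ]
  pairs <- merge(inp, cfc, by = c("patient_id", "gene_id", "variant_label"),
                 suffixes = c("_input", "_cfchip"))
  dropped <- nrow(inp) + nrow(cfc) - 2L * nrow(pairs)
  if (dropped > 0)
    message(dropped, " unpaired variant record(s) dropped")
  pairs <- pairs[order(pairs$patient_id, pairs$variant_label), ]
  data.frame(patient_id = pairs$patient_id, gene_id = pairs$gene_id,
             variant_label = pairs$variant_label,
             maf_input = pairs$maf_input, maf_cfchip = pairs$maf_cfchip,
             depth_input = pairs$total_depth_input,
             depth_cfchip = pairs$total_depth_cfchip, row.names = NULL)
}

#' Paired MAF comparison between cfChIP and input
#'
#' Per-pair difference \code{d = maf_cfchip - maf_input} expressed in
#' percentage points; reports the mean difference, the t-based 95 percent
#' confidence interval, the two-sided paired t-test p-value, and the counts
#' of pairs shifting up versus down. When all differences are identical the
#' CI degenerates to a point and p follows the zero-variance convention
#' (1 when the common difference is 0, else 0 with a warning).
#'
#' @param pairs data.frame from [pairVariants()].
#' @param gene optional gene id filter (e.g. \code{"TP53"}).
#' @return a [PairedMafResult]
#' @export
pairedMafTest <- function(pairs, gene = NULL) {
  if (!is.null(gene)) pairs <- pairs[pairs$gene_id == gene, ]
  if (nrow(pairs) < 2L) stop("need at least 2 pairs for a paired test")
  d <- (pairs$maf_cfchip - pairs$maf_input) * 100

  if (stats::sd(d) == 0) {
    p <- if (d[1] == 0) 1 else {
      warning("all per-pair differences identical and non-zero; p set to 0")
      0
    }
    ci <- c(mean(d), mean(d))
  } else {
    tt <- stats::t.test(d)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  }

  new("PairedMafResult",
      n_pairs = nrow(pairs),
      mean_difference = mean(d),
      ci95 = ci, p_value = p,
      direction = c(positive = sum(d > 0), negative = sum(d < 0),
                    zero = sum(d == 0)),
      differences = d)
}

#' Frequency of a mutated gene across patients
#'
#' Fraction of patients carrying at least one variant record of the given
#' gene (in any compartment).
#'
#' @param variants a [VariantTable] or data.frame.
#' @param gene gene id (e.g. \code{"TP53"}).
#' @param nPatients total number of patients screened; defaults to the number
#'   of distinct patients in the table.
#' @return list with \code{n_mutated}, \code{n_patients} and \code{frequency}
#'   (a fraction in [0, 1]).
#' @export
mutationPrevalence <- function(variants, gene, nPatients = NULL) {
  v <- if (methods::is(variants, "VariantTable")) variantRecords(variants)
       else as.data.frame(variants)
  if (is.null(nPatients)) nPatients <- length(unique(v$patient_id))
  nMut <- length(unique(v$patient_id[v$gene_id == gene]))
  list(n_mutated = nMut, n_patients = nPatients,
       frequency = nMut / nPatients)
}

#' Read a variant table
#'
#' Tab-separated columns \code{patient_id}, \code{gene_id},
#' \code{variant_label}, \code{compartment}, \code{alt_depth},
#' \code{total_depth}.
#'
#' @param path file path.
#' @return a [VariantTable]
#' @export
readVariantTable <- function(path) {
  VariantTable(utils::read.delim(path, stringsAsFactors = FALSE))
}
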