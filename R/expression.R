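## Differential expression from TPM matrices: log2(TPM+1) transform,
## activity filter, mean-of-logs fold change, per-gene Welch t-test with
## Benjamini-Hochberg FDR.

#' log2(TPM + 1) transform
#'
#' @param tpm a [TpmMatrix], matrix or numeric vector of non-negative TPM
#'   values.
#' @return object of the same shape with \code{log2(x + 1)} values.
#' @export
logTransform <- function(tpm) {
  x <- if (methods::is(tpm, "TpmMatrix"))
    SummarizedExperiment::assay(tpm, "tpm") else tpm
  if (any(x < 0)) stop("TPM values must be non-negative")
  log2(x + 1)
}

## genes x groups matrix of group-mean log2(TPM+1)
groupMeanLog <- function(tpm, groups = NULL) {
  lt <- logTransform(tpm)
  grp <- SummarizedExperiment::colData(tpm)$group
  if (is.null(groups)) groups <- unique(grp)
  out <- vapply(groups, function(g) {
    if (!any(grp == g)) stop("group not found: ", g)
    rowMeans(lt[, grp == g, drop = FALSE])
  }, numeric(nrow(lt)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(rownames(lt), groups)
  out
}

#' Classify genes as transcriptionally active or inactive
#'
#' A gene is active in a group when its group-mean \eqn{\log_2(TPM+1)}
#' strictly exceeds \code{threshold}. Genes inactive in \emph{both} groups are
#' removed before differential expression testing.
#'
#' @param tpm a [TpmMatrix].
#' @param groupA,groupB group labels present in \code{colData(tpm)$group}.
#' @param threshold activity cutoff on the \eqn{\log_2(TPM+1)} scale;
#'   default 0.2.
#' @return data.frame with columns \code{gene_id}, \code{active_a},
#'   \code{active_b}, \code{retained}.
#' @export
classifyActive <- function(tpm, groupA, groupB, threshold = 0.2) {
  gm <- groupMeanLog(tpm, c(groupA, groupB))
  data.frame(gene_id = rownames(gm),
             active_a = gm[, 1] > threshold,
             active_b = gm[, 2] > threshold,
             retained = gm[, 1] > threshold | gm[, 2] > threshold,
             row.names = NULL)
}

#' Expression log2 fold change (difference of mean logs)
#'
#' \eqn{\log_2 FC = \overline{\log_2(TPM^a+1)} - \overline{\log_2(TPM^b+1)}}:
#' the difference of group means of the log-transformed values (mean of logs,
#' not log of mean TPM).
#'
#' @param groupAValues,groupBValues numeric vectors of replicate TPM values
#'   for one gene.
#' @return numeric log2 fold change (positive = higher in group a).
#' @export
expressionLog2FC <- function(groupAValues, groupBValues) {
  if (length(groupAValues) == 0L || length(groupBValues) == 0L)
    stop("empty group")
  mean(logTransform(groupAValues)) - mean(logTransform(groupBValues))
}

## Welch two-sided p-value with the degenerate-variance convention:
## both groups constant -> p = 1 if means equal, else p = 0 (warning).
welchP <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(1)
    warning("zero variance in both groups with unequal means; p set to 0")
    return(0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Differential expression between two groups
#'
#' Applies the activity filter (genes inactive in both groups are excluded),
#' computes the mean-of-logs fold change, tests each retained gene with a
#' two-sided Welch t-test on the \eqn{\log_2(TPM+1)} replicate values, and
#' adjusts p-values with Benjamini-Hochberg across the retained genes only.
#' Status is \code{up_in_a} when \code{log2fc > fcThreshold} and
#' \code{q < qThreshold}, \code{up_in_b} for the mirrored condition,
#' \code{not_de} otherwise, and \code{filtered_inactive} (no p/q) for genes
#' failing the activity filter.
#'
#' @param tpm a [TpmMatrix].
#' @param groupA,groupB group labels in \code{colData(tpm)$group}.
#' @param fcThreshold absolute log2 fold-change cutoff; default 1.
#' @param qThreshold FDR cutoff; default 0.05.
#' @param activityThreshold activity cutoff passed to [classifyActive()].
#' @return data.frame with columns \code{gene_id}, \code{log2fc},
#'   \code{p_value}, \code{q_value}, \code{status}.
#' @export
differentialExpression <- function(tpm, groupA, groupB, fcThreshold = 1,
                                   qThreshold = 0.05,
                                   activityThreshold = 0.2) {
  lt <- logTransform(tpm)
  grp <- SummarizedExperiment::colData(tpm)$group
  ia <- grp == groupA
  ib <- grp == groupB
  if (sum(ia) < 2L || sum(ib) < 2L)
    stop("cannot estimate variance: each group needs >= 2 replicates")

  act <- classifyActive(tpm, groupA, groupB, activityThreshold)
  log2fc <- rowMeans(lt[, ia, drop = FALSE]) -
            rowMeans(lt[, ib, drop = FALSE])

  p <- rep(NA_real_, nrow(lt))
  tested <- act$retained
  p[tested] <- vapply(which(tested), function(i)
    welchP(lt[i, ia], lt[i, ib]), numeric(1))
  q <- rep(NA_real_, nrow(lt))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")

  status <- rep("not_de", nrow(lt))
  status[!tested] <- "filtered_inactive"
  status[tested & log2fc > fcThreshold & q < qThreshold] <- "up_in_a"
  status[tested & log2fc < -fcThreshold & q < qThreshold] <- "up_in_b"

  data.frame(gene_id = rownames(lt), log2fc = log2fc, p_value = p,
             q_value = q, status = status, row.names = NULL)
}
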