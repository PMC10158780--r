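## Concordance between enrichment and expression: rank correlation, ROC
## analysis of active-gene discrimination, sensitivity at fixed specificity,
## and the differential-expression vs differential-enrichment agreement
## statistics.

#' Spearman rank correlation with AS 89 / exact permutation p-value
#'
#' Rank correlation with average ranks for ties. The p-value comes from
#' \code{stats::cor.test}: the exact permutation distribution for small
#' untied samples, otherwise the AS 89 approximation.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with \code{rho}, \code{p_value} and \code{n}.
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' ROC analysis of active-gene discrimination
#'
#' Treats per-gene enrichment as a score for predicting transcriptional
#' activity. AUC is computed through the Mann-Whitney identity (rank form,
#' ties weighted 1/2), its standard error with the Hanley-McNeil (1982)
#' formula, and the two-tailed p-value from the z-ratio
#' \eqn{(AUC - 0.5)/SE}. The ROC curve is the step curve over the distinct
#' observed scores (no smoothing or interpolation).
#'
#' @param scores numeric per-gene enrichment values.
#' @param labels logical (\code{TRUE} = active) or character
#'   (\code{"active"}/\code{"inactive"}) of the same length.
#' @return a [RocResult]
#' @export
rocActiveGenes <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "active"
  stopifnot(length(scores) == length(labels))
  act <- scores[labels]
  inact <- scores[!labels]
  n1 <- length(act)
  n0 <- length(inact)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")

  # Mann-Whitney via average ranks: ties contribute 1/2 automatically
  r <- rank(c(act, inact))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
              (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- if (se > 0) (auc - 0.5) / se else sign(auc - 0.5) * Inf
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  curve <- data.frame(
    threshold = thr,
    specificity = vapply(thr, function(t) mean(inact < t), numeric(1)),
    sensitivity = vapply(thr, function(t) mean(act >= t), numeric(1))
  )

  new("RocResult", auc = auc, se = se, z = z, p_value = p, curve = curve,
      n_active = n1, n_inactive = n0)
}

#' Sensitivity at a specificity cut-off
#'
#' The maximum sensitivity among step-curve operating points whose
#' specificity is at least \code{cutoff} (no interpolation).
#'
#' @param roc a [RocResult].
#' @param cutoff required specificity; default 0.75.
#' @return numeric sensitivity in [0, 1] (0 when no threshold qualifies).
#' @export
sensitivityAtSpecificity <- function(roc, cutoff = 0.75) {
  ok <- roc@curve$specificity >= cutoff
  if (!any(ok)) return(0)
  max(roc@curve$sensitivity[ok])
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Probability-mass two-sided convention: the p-value sums hypergeometric
#' probabilities, at fixed margins, of all tables no more probable than the
#' observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  if (sum(table) == 0) stop("all-zero table")
  stats::fisher.test(table)$p.value
}

#' Agreement between differential expression and differential enrichment
#'
#' A differentially expressed gene agrees with the enrichment assay when its
#' relative enrichment log2 fold change points in the same direction:
#' strictly positive for \code{up_in_a} genes, strictly negative for
#' \code{up_in_b} genes; exact zeros count as disagreement (with a warning).
#' Per-direction sensitivity is the agreeing fraction, and the 2x2 table of
#' DE direction against enrichment sign is tested with Fisher's exact test.
#'
#' @param de data.frame as returned by [differentialExpression()] (columns
#'   \code{gene_id} and \code{status} are used).
#' @param enrichmentLog2fc named numeric vector of relative enrichment log2
#'   fold changes (positive = enriched in group a), covering every DE gene.
#' @return an [AgreementResult]
#' @export
agreementAnalysis <- function(de, enrichmentLog2fc) {
  upA <- de$gene_id[de$status == "up_in_a"]
  upB <- de$gene_id[de$status == "up_in_b"]
  missing <- setdiff(c(upA, upB), names(enrichmentLog2fc))
  if (length(missing))
    stop("DE gene(s) missing from the enrichment vector: ",
         paste(utils::head(missing, 5), collapse = ", "))

  fcA <- enrichmentLog2fc[upA]
  fcB <- enrichmentLog2fc[upB]
  nZero <- sum(fcA == 0) + sum(fcB == 0)
  if (nZero > 0)
    warning(nZero, " DE gene(s) with zero enrichment log2FC counted as ",
            "disagreement")

  contingency <- matrix(
    c(sum(fcA > 0), sum(fcA <= 0),
      sum(fcB > 0), sum(fcB <= 0)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("up_in_a", "up_in_b"),
                    c("enrich_positive", "enrich_nonpositive")))

  sens <- c(
    up_in_a = if (length(upA)) sum(fcA > 0) / length(upA) else NA_real_,
    up_in_b = if (length(upB)) sum(fcB < 0) / length(upB) else NA_real_)

  fp <- if (sum(contingency) > 0) fisherExact2x2(contingency) else NA_real_

  new("AgreementResult", sensitivity = sens,
      contingency = contingency, fisher_p = fp,
      geneLists = list(
        up_in_a_positive = upA[fcA > 0],
        up_in_a_nonpositive = upA[fcA <= 0],
        up_in_b_positive = upB[fcB > 0],
        up_in_b_nonpositive = upB[fcB <= 0]),
      n_zero = as.integer(nZero))
}

#' Agreement accessors
#'
#' @param x an [AgreementResult]
#' @return \code{agreementSensitivity}: named numeric per-direction
#'   sensitivities; \code{agreementTable}: the 2x2 contingency matrix;
#'   \code{agreementFisherP}: the Fisher's exact p-value.
#' @export
agreementSensitivity <- function(x) x@sensitivity

#' @rdname agreementSensitivity
#' @export
agreementTable <- function(x) x@contingency

#' @rdname agreementSensitivity
#' @export
agreementFisherP <- function(x) x@fisher_p
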