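# Shared fixture builders. Everything is generated in code; no data files.

# Minimal panel: all genes '+' strand, generously long, fully included.
simplePanel <- function(k, name = "test-panel") {
  ids <- names(k)
  tab <- data.frame(gene_id = ids, chrom = "chr1", strand = "+",
                    tss = seq(0, by = 1e6, length.out = length(k)),
                    gene_length = 100000L, k = as.integer(k),
                    stringsAsFactors = FALSE)
  suppressWarnings(buildPanel(tab, name = name))
}

countsOf <- function(m, condition = "s", assayType = "chip") {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (length(condition) == 1L) condition <- rep(condition, ncol(m))
  CfChipCounts(m, condition = condition, assayType = assayType)
}

# TPM matrix with two groups "a" and "b" from per-group replicate matrices.
tpmOf <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  m <- cbind(a, b)
  colnames(m) <- c(paste0("a", seq_len(ncol(a))), paste0("b", seq_len(ncol(b))))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  TpmMatrix(m, group = rep(c("a", "b"), c(ncol(a), ncol(b))))
}

# All permutations of a small vector (for exhaustive rank-permutation oracles).
allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in allPerms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Two-sided Fisher p by hypergeometric enumeration (probability-mass method).
fisherOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  pObs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Welch two-sided p from the closed-form statistic (independent of t.test).
welchOracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# Worked agreement example: TPM matrices engineered so differential
# expression yields exactly nA up_in_a and nB up_in_b genes, and enrichment
# group means whose relative log2FC is concordant for okA / okB of them.
agreementWorkedExample <- function(nA, okA, nB, okB, seed = 1L) {
  set.seed(seed)
  nFiller <- 20L
  ids <- sprintf("gene%03d", seq_len(nA + nB + nFiller))
  upA <- ids[seq_len(nA)]
  upB <- ids[nA + seq_len(nB)]
  base <- matrix(2, length(ids), 3)  # log2(TPM+1) baseline, active everywhere
  la <- base; lb <- base
  la[match(upA, ids), ] <- 5
  lb[match(upB, ids), ] <- 5
  noise <- function(m) m + matrix(rnorm(length(m), 0, 0.05), nrow(m))
  tpmMat <- pmax(2^cbind(noise(la), noise(lb)) - 1, 0)
  rownames(tpmMat) <- ids
  colnames(tpmMat) <- c(paste0("a", 1:3), paste0("b", 1:3))
  de <- differentialExpression(TpmMatrix(tpmMat, rep(c("a", "b"), each = 3)),
                               "a", "b")
  stopifnot(sum(de$status == "up_in_a") == nA,
            sum(de$status == "up_in_b") == nB)

  mA <- setNames(rep(1, length(ids)), ids)
  mB <- mA
  mA[upA[seq_len(okA)]] <- 4                      # concordant: up in a
  if (okA < nA) mB[upA[(okA + 1):nA]] <- 4        # discordant
  mB[upB[seq_len(okB)]] <- 4                      # concordant: up in b
  if (okB < nB) mA[upB[(okB + 1):nB]] <- 4        # discordant
  fc <- relativeLog2FC(mA, mB, pseudo = 1e-3)
  agreementAnalysis(de, fc)
}

# AUC by brute-force pair counting, ties counted 1/2.
aucOracle <- function(scores, labels) {
  act <- scores[labels]; inact <- scores[!labels]
  s <- 0
  for (x in act) for (y in inact) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(act) * length(inact))
}
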