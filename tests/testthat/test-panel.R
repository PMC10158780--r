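test_that("coverage factor counts bases strictly above the depth threshold", {
  expect_equal(computeCoverageFactor(rep(200L, 500)), 500L)
  expect_equal(computeCoverageFactor(rep(100L, 500)), 0L)  # strict >
  expect_equal(computeCoverageFactor(c(rep(150L, 300), rep(50L, 200))), 300L)
  expect_error(computeCoverageFactor(integer(0)), "no captured bases")
})

test_that("coverage factor is monotone non-increasing in the threshold", {
  set.seed(11)
  for (i in 1:20) {
    depths <- rpois(200, lambda = sample(50:300, 1))
    ks <- vapply(c(0, 50, 100, 150, 300), function(th)
      computeCoverageFactor(depths, th), integer(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("TSS-window exclusion follows the strand-aware 25% rule", {
  # '+' gene: window is [1000, 3500)
  expect_true(flagTssExcluded(cbind(1100, 1500), tss = 1000, strand = "+",
                              geneLength = 10000))
  expect_false(flagTssExcluded(rbind(c(1100, 1500), c(8000, 8200)),
                               tss = 1000, strand = "+", geneLength = 10000))
  # '-' gene: window walks 10000 -> 7501
  expect_true(flagTssExcluded(cbind(9000, 9900), tss = 10000, strand = "-",
                              geneLength = 10000))
  expect_error(flagTssExcluded(cbind(20000, 20100), tss = 1000,
                               strand = "+", geneLength = 10000),
               "capture outside gene")
})

test_that("'-' strand window matches enumeration of covered positions", {
  # every covered base's walking distance from the TSS must be < floor(L/4)
  tss <- 10000; L <- 10000
  iv <- cbind(9000, 9900)
  bases <- seq(iv[1], iv[2] - 1)
  dist <- tss - bases  # steps walked from TSS towards lower coordinates
  expect_equal(all(dist >= 0 & dist < floor(0.25 * L)),
               flagTssExcluded(iv, tss, "-", L))
  iv2 <- cbind(7000, 7600)  # partially beyond the window
  bases2 <- seq(iv2[1], iv2[2] - 1)
  expect_equal(all(tss - bases2 < floor(0.25 * L)),
               flagTssExcluded(iv2, tss, "-", L))
})

test_that("TSS exclusion is strand-symmetric on mirrored geometries", {
  set.seed(7)
  for (i in 1:50) {
    L <- sample(2000:50000, 1)
    tss <- sample(1e5:2e5, 1)
    nIv <- sample(1:3, 1)
    st <- sort(sample(0:(L - 20), nIv))
    en <- st + sample(10:19, nIv, replace = TRUE)
    plus <- cbind(tss + st, tss + en)
    # mirror every base p -> M - p; half-open [s,e) -> [M-e+1, M-s+1)
    M <- 5e5
    minus <- cbind(M - plus[, 2] + 1, M - plus[, 1] + 1)
    expect_equal(flagTssExcluded(plus, tss, "+", L),
                 flagTssExcluded(minus, M - tss, "-", L))
  }
})

test_that("buildPanel assembles, flags and validates", {
  tab <- data.frame(gene_id = c("A", "B", "C"), chrom = "chr1",
                    strand = "+", tss = c(0, 1e6, 2e6),
                    gene_length = 50000L, k = c(1000L, 2000L, 3000L))
  p <- buildPanel(tab)
  expect_s4_class(p, "GenePanel")
  expect_equal(length(p), 3L)
  expect_equal(includedGenes(p), c("A", "B", "C"))

  tab$k[2] <- 0L
  expect_warning(p0 <- buildPanel(tab), "k = 0")
  expect_false(panelGenes(p0)$included[2])
  expect_equal(includedGenes(p0), c("A", "C"))

  tab$gene_id[2] <- "A"
  expect_error(suppressWarnings(buildPanel(tab)), "duplicate gene_id")

  expect_error(buildPanel(data.frame(gene_id = "A", chrom = "chr1",
                                     strand = "+", tss = 0,
                                     gene_length = 1000L)),
               "cannot compute coverage factors")
})

test_that("coverage factors can be computed from depth profiles", {
  tab <- data.frame(gene_id = c("A", "B"), chrom = "chr1", strand = "+",
                    tss = c(0, 1e6), gene_length = 50000L)
  prof <- list(A = rep(200L, 400), B = c(rep(150L, 100), rep(20L, 900)))
  p <- buildPanel(tab, depthProfiles = prof)
  expect_equal(unname(coverageFactors(p)), c(400L, 100L))
})

test_that("a 197-gene panel with 36 TSS-only geometries keeps 161 genes", {
  n <- 197L
  ids <- sprintf("g%03d", 1:n)
  L <- 40000L
  tss <- (seq_len(n) - 1) * 1e5
  k <- 2000L
  start <- ifelse(seq_len(n) <= 36, tss,        # inside [tss, tss+10000)
                  tss + floor(0.25 * L))        # starts at the window edge
  bed <- data.frame(chrom = "chr1", start = start, end = start + k,
                    gene_id = ids)
  tab <- data.frame(gene_id = ids, chrom = "chr1", strand = "+", tss = tss,
                    gene_length = L, k = k)
  p <- buildPanel(tab, captureIntervals = bed)
  expect_equal(sum(panelGenes(p)$tss_excluded), 36L)
  expect_equal(length(includedGenes(p)), 161L)
})

test_that("rebuilding a panel from its serialized output is idempotent", {
  cfg <- simulationConfig(nGenes = 40L, nTssExcluded = 8L, seed = 5L)
  p <- simulatePanel(cfg)
  f <- tempfile(fileext = ".tsv")
  writePanel(p, f)
  p2 <- buildPanel(readPanelTable(f), name = p@name)
  expect_equal(panelGenes(p2), panelGenes(p))
  f2 <- tempfile(fileext = ".tsv")
  writePanel(p2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("overlapping capture intervals are merged before flagging", {
  bed <- data.frame(chrom = "chr1", start = c(100, 150, 400),
                    end = c(200, 250, 500), gene_id = "A")
  tab <- data.frame(gene_id = "A", chrom = "chr1", strand = "+", tss = 0,
                    gene_length = 10000L, k = 250L)
  p <- buildPanel(tab, captureIntervals = bed)
  iv <- captureIntervals(p)
  expect_equal(length(iv), 2L)  # [100,250) and [400,500)
  expect_true(panelGenes(p)$tss_excluded[1])  # all bases < 2500
})
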