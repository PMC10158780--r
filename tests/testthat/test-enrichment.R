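test_that("chip enrichment matches closed forms and conserves sum(E*k)", {
  p <- simplePanel(c(A = 1000, B = 9000))
  cnt <- countsOf(matrix(c(100, 900), ncol = 1, dimnames = list(c("A", "B"))))
  e <- chipEnrichment(cnt, p)
  expect_equal(unname(e@values[, 1]), c(1e5, 1e5))  # equal per-base rates
  expect_equal(sum(e@values[, 1] * c(1000, 9000)), 1e9)

  p1 <- simplePanel(c(A = 500))
  c1 <- countsOf(matrix(50, dimnames = list("A")))
  expect_equal(unname(chipEnrichment(c1, p1)@values[1, 1]), 2e6)

  expect_error(chipEnrichment(countsOf(matrix(0, dimnames = list("A"))), p1),
               "empty sample")
})

test_that("chip enrichment equals the literal per-gene formula", {
  set.seed(21)
  k <- setNames(sample(500:5000, 10), paste0("g", 1:10))
  p <- simplePanel(k)
  n <- matrix(rpois(10, 2000), ncol = 1, dimnames = list(names(k)))
  e <- chipEnrichment(countsOf(n), p)
  total <- sum(n)
  oracle <- vapply(seq_len(10), function(i) n[i, 1] * 1e9 / (total * k[i]),
                   numeric(1))
  expect_equal(unname(e@values[, 1]), oracle)
})

test_that("chip enrichment is invariant to sequencing depth scaling", {
  set.seed(22)
  k <- setNames(sample(500:5000, 8), paste0("g", 1:8))
  p <- simplePanel(k)
  n <- matrix(rpois(8, 1000), ncol = 1, dimnames = list(names(k)))
  e1 <- chipEnrichment(countsOf(n), p)
  e2 <- chipEnrichment(countsOf(n * 7), p)
  expect_equal(e1@values, e2@values)
})

test_that("background profile is the arithmetic donor mean", {
  p <- simplePanel(c(A = 1000))
  m <- matrix(c(10, 30), nrow = 1, dimnames = list("A", c("h1", "h2")))
  bg <- makeBackground(countsOf(m, condition = "healthy",
                                assayType = "cfchip"), p)
  expect_equal(unname(bg@meanCounts), 20)
  expect_equal(bg@nDonors, 2L)

  bg1 <- makeBackground(countsOf(m[, 1, drop = FALSE], "healthy", "cfchip"), p)
  expect_equal(unname(bg1@meanCounts), 10)

  set.seed(23)
  k5 <- setNames(rep(1000, 5), paste0("g", 1:5))
  p5 <- simplePanel(k5)
  m5 <- matrix(rpois(20, 100), nrow = 5, dimnames = list(names(k5), NULL))
  bg5 <- makeBackground(countsOf(m5, "healthy", "cfchip"), p5)
  expect_equal(bg5@totalMean, mean(colSums(m5)))  # sum both ways

  expect_error(makeBackground(countsOf(m, "NSCLC", "cfchip"), p),
               "no healthy samples")
})

test_that("background-subtracted enrichment matches closed forms", {
  p <- simplePanel(c(A = 1000, B = 1000))
  bg <- new("BackgroundProfile", gene_id = c("A", "B"),
            meanCounts = c(A = 100, B = 100), totalMean = 200, nDonors = 4L)
  cnt <- countsOf(matrix(c(300, 100), ncol = 1,
                         dimnames = list(c("A", "B"))), "x", "cfchip")
  e <- cfchipRelativeEnrichment(cnt, bg, p)
  expect_equal(unname(e@values[, 1]), c(1e6, 0))  # B cancels exactly
  expect_equal(e@kind, "cfchip_relative")

  # patient identical to background except one gene +d -> E = 1e9/k there
  d <- 57
  cnt2 <- countsOf(matrix(c(100 + d, 100), ncol = 1,
                          dimnames = list(c("A", "B"))), "x", "cfchip")
  e2 <- cfchipRelativeEnrichment(cnt2, bg, p)
  expect_equal(unname(e2@values[, 1]), c(1e9 / 1000, 0))

  expect_error(
    cfchipRelativeEnrichment(countsOf(matrix(c(150, 50), ncol = 1,
                                             dimnames = list(c("A", "B"))),
                                      "x", "cfchip"), bg, p),
    "degenerate background-subtracted library size")
})

test_that("background-subtracted enrichment matches the literal formula", {
  set.seed(24)
  k <- setNames(sample(500:5000, 20), paste0("g", 1:20))
  p <- simplePanel(k)
  h <- setNames(rpois(20, 150), names(k))
  bg <- new("BackgroundProfile", gene_id = names(k), meanCounts = h,
            totalMean = sum(h), nDonors = 4L)
  n <- matrix(rpois(20, 400), ncol = 1, dimnames = list(names(k)))
  e <- cfchipRelativeEnrichment(countsOf(n, "x", "cfchip"), bg, p)
  denom <- sum(n) - sum(h)
  oracle <- vapply(seq_len(20), function(i)
    (n[i, 1] - h[i]) * 1e9 / (denom * k[i]), numeric(1))
  expect_equal(unname(e@values[, 1]), oracle)
  # conservation holds for the subtracted form too
  expect_equal(sum(e@values[, 1] * k), 1e9, tolerance = 1e-9)
})

test_that("an all-zero background reduces the subtracted form to Eq. 2", {
  set.seed(25)
  k <- setNames(sample(500:3000, 6), paste0("g", 1:6))
  p <- simplePanel(k)
  n <- matrix(rpois(6, 500), ncol = 1, dimnames = list(names(k)))
  bg0 <- new("BackgroundProfile", gene_id = names(k),
             meanCounts = setNames(rep(0, 6), names(k)), totalMean = 0,
             nDonors = 1L)
  eRel <- cfchipRelativeEnrichment(countsOf(n, "x", "cfchip"), bg0, p)
  eChip <- chipEnrichment(countsOf(n), p)
  expect_identical(unname(eRel@values), unname(eChip@values))
})

test_that("conservation sum(E*k) = 1e9 holds on simulated samples", {
  cfg <- simulationConfig(nGenes = 50L, nTssExcluded = 8L, seed = 31L)
  ds <- simulateDataset(cfg)
  k <- coverageFactors(ds@panel)[includedGenes(ds@panel)]

  e2 <- chipEnrichment(ds@counts, ds@panel,
                       samples = c("NSCLC_rep1", "SCLC_rep2"))
  expect_true(all(abs(colSums(e2@values * k) / 1e9 - 1) < 1e-6))

  bg <- makeBackground(ds@counts, ds@panel)
  cd <- SummarizedExperiment::colData(ds@counts)
  pat <- rownames(cd)[cd$assay_type == "cfchip" & cd$condition != "healthy"]
  e3 <- cfchipRelativeEnrichment(ds@counts, bg, ds@panel, samples = pat)
  expect_true(all(abs(colSums(e3@values * k) / 1e9 - 1) < 1e-6))
})

test_that("relative log2 fold change behaves like a signed ratio", {
  a <- setNames(c(4, 8, 1), c("x", "y", "z"))
  expect_equal(unname(relativeLog2FC(a, a, pseudo = 1e-6)), c(0, 0, 0))

  b <- setNames(c(1, 2, 0.25), names(a))  # a = 4x
  fc <- relativeLog2FC(a, b, pseudo = 1e-9)
  expect_equal(unname(fc), rep(2, 3), tolerance = 1e-6)
  expect_equal(relativeLog2FC(b, a, pseudo = 1e-9),
               -relativeLog2FC(a, b, pseudo = 1e-9))

  expect_error(relativeLog2FC(a, setNames(b, c("x", "y", "w"))),
               "different gene sets")
})

test_that("negative group means are clamped and the default pseudo applies", {
  a <- setNames(c(-5, 2), c("x", "y"))
  b <- setNames(c(1, 2), c("x", "y"))
  # smallest positive mean is 1 -> pseudo 0.5; x: log2(0.5) - log2(1.5)
  fc <- relativeLog2FC(a, b)
  expect_equal(unname(fc[1]), log2(0.5) - log2(1.5))
  expect_equal(unname(fc[2]), 0)
})

test_that("enrichment profiles round-trip through TSV", {
  set.seed(26)
  k <- setNames(sample(500:3000, 4), paste0("g", 1:4))
  p <- simplePanel(k)
  n <- matrix(rpois(8, 300), ncol = 2,
              dimnames = list(names(k), c("s1", "s2")))
  e <- chipEnrichment(countsOf(n), p)
  f <- tempfile(fileext = ".tsv")
  writeEnrichment(e, f)
  e2 <- readEnrichment(f)
  expect_equal(e2@kind, "chip")
  expect_equal(e2@values, e@values, tolerance = 1e-12)
})
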