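## Panel construction: coverage factors, capture geometry, TSS-window exclusion.
## Coordinates are 0-based half-open (BED convention) throughout.

#' Coverage factor from a per-base depth profile
#'
#' The coverage factor \eqn{k_i} of a gene is the number of captured bases
#' sequenced above a reference depth in a calibration capture experiment
#' (purified genomic DNA applied to the panel). It is the per-gene length
#' normalizer in the enrichment formulas.
#'
#' @param depthProfile integer vector of per-base read depths over the gene's
#'   captured bases.
#' @param depthThreshold bases with depth strictly greater than this count
#'   towards \eqn{k_i}. Default 100.
#' @return integer number of bases with depth > \code{depthThreshold}.
#' @examples
#' computeCoverageFactor(rep(200L, 500))        # 500
#' computeCoverageFactor(rep(100L, 500))        # 0: strictly greater
#' @export
computeCoverageFactor <- function(depthProfile, depthThreshold = 100L) {
  if (length(depthProfile) == 0L) stop("no captured bases")
  if (depthThreshold < 0) stop("depthThreshold must be >= 0")
  as.integer(sum(depthProfile > depthThreshold))
}

## Strand-aware TSS-proximal window, 0-based half-open: the first
## floor(fraction * gene_length) bases of the gene body walking from the TSS
## in the direction of transcription.
tssWindow <- function(tss, strand, geneLength, fraction) {
  w <- floor(fraction * geneLength)
  if (strand == "+") c(tss, tss + w) else c(tss - w + 1, tss + 1)
}

geneBody <- function(tss, strand, geneLength) {
  if (strand == "+") c(tss, tss + geneLength)
  else c(tss - geneLength + 1, tss + 1)
}

#' Is a gene captured only near its TSS?
#'
#' H3K36me3 accumulates over the 3' portion of transcribed gene bodies and is
#' depleted near the TSS, so genes whose capture probes tile only the
#' TSS-proximal window cannot report transcription and are excluded from
#' enrichment analysis. A gene is flagged iff \emph{every} captured base lies
#' within the first \code{fraction} of the gene body measured from the TSS in
#' the direction of transcription.
#'
#' @param intervals two-column matrix or data.frame of 0-based half-open
#'   (start, end) captured intervals.
#' @param tss 0-based coordinate of the transcription start site.
#' @param strand \code{"+"} or \code{"-"}; for \code{"-"} the window extends
#'   from \code{tss} towards lower coordinates.
#' @param geneLength gene body length in bp (> 0).
#' @param fraction window size as a fraction of the gene body; default 0.25.
#' @return logical: \code{TRUE} when the gene is captured solely within the
#'   TSS window.
#' @export
flagTssExcluded <- function(intervals, tss, strand, geneLength,
                            fraction = 0.25) {
  intervals <- as.matrix(intervals)
  if (nrow(intervals) == 0L) stop("captured_intervals must be non-empty")
  if (geneLength <= 0) stop("gene_length must be > 0")
  if (any(intervals[, 2] <= intervals[, 1]))
    stop("intervals must be half-open with end > start")
  body <- geneBody(tss, strand, geneLength)
  if (any(intervals[, 1] < body[1]) || any(intervals[, 2] > body[2]))
    stop("capture outside gene")
  win <- tssWindow(tss, strand, geneLength, fraction)
  all(intervals[, 1] >= win[1] & intervals[, 2] <= win[2])
}

#' Build a gene panel
#'
#' Assembles a [GenePanel] from a per-gene annotation table, optional capture
#' geometry and optional calibration depth profiles. Coverage factors are
#' taken from the table's \code{k} column when present, otherwise computed
#' from \code{depthProfiles} via [computeCoverageFactor()]. A gene is included
#' in enrichment computations iff it is not TSS-window excluded and has
#' \eqn{k > 0}; genes with \eqn{k = 0} are retained in the panel (with a
#' warning) but never enter enrichment sums.
#'
#' @param panelTable data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tss}, \code{gene_length} and optionally \code{k}.
#' @param captureIntervals optional capture geometry: a \code{GRanges} with a
#'   \code{gene_id} metadata column, or a data.frame with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{gene_id} (BED-like, 0-based
#'   half-open). Overlapping intervals are merged per gene.
#' @param depthProfiles optional named list (by gene_id) of per-base depth
#'   vectors used to compute \code{k} when the table lacks it.
#' @param depthThreshold depth cutoff for [computeCoverageFactor()]; default 100.
#' @param tssFraction TSS-window fraction for [flagTssExcluded()]; default 0.25.
#' @param name panel name.
#' @return a [GenePanel]
#' @export
buildPanel <- function(panelTable, captureIntervals = NULL,
                       depthProfiles = NULL, depthThreshold = 100L,
                       tssFraction = 0.25, name = "panel") {
  need <- c("gene_id", "chrom", "strand", "tss", "gene_length")
  if (!all(need %in% names(panelTable)))
    stop("panel table is missing columns: ",
         paste(setdiff(need, names(panelTable)), collapse = ", "))
  g <- as.data.frame(panelTable)
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in panel table: ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))

  gr <- normalizeCaptureIntervals(captureIntervals)

  if (!"k" %in% names(g)) {
    if (is.null(depthProfiles))
      stop("no 'k' column and no depth profiles: cannot compute coverage factors")
    missing <- setdiff(g$gene_id, names(depthProfiles))
    if (length(missing))
      stop("no depth profile for gene(s): ", paste(missing, collapse = ", "))
    g$k <- vapply(g$gene_id, function(id)
      computeCoverageFactor(depthProfiles[[id]], depthThreshold), integer(1))
  }
  g$k <- as.integer(g$k)

  # precomputed flag (e.g. a re-read serialized panel) is honored where no
  # geometry is available; geometry unknown and no flag -> cannot assess
  prior <- if ("tss_excluded" %in% names(g)) as.logical(g$tss_excluded)
           else rep(FALSE, nrow(g))
  g$tss_excluded <- vapply(seq_len(nrow(g)), function(i) {
    iv <- intervalsForGene(gr, g$gene_id[i])
    if (is.null(iv)) return(prior[i])
    flagTssExcluded(iv, g$tss[i], g$strand[i], g$gene_length[i], tssFraction)
  }, logical(1))

  if (!is.null(gr)) {
    capt <- vapply(seq_len(nrow(g)), function(i) {
      iv <- intervalsForGene(gr, g$gene_id[i])
      if (is.null(iv)) NA_real_ else sum(iv[, 2] - iv[, 1])
    }, numeric(1))
    over <- which(!is.na(capt) & g$k > capt)
    if (length(over))
      stop("coverage factor exceeds captured bases for: ",
           paste(g$gene_id[over], collapse = ", "))
  }

  if (any(g$k == 0))
    warning(sum(g$k == 0), " gene(s) with k = 0 retained but excluded ",
            "from enrichment sums")
  g$included <- !g$tss_excluded & g$k > 0

  new("GenePanel", genes = g,
      intervals = if (is.null(gr)) GenomicRanges::GRanges() else gr,
      name = name)
}

## Accepts GRanges, BED-like data.frame, or NULL; returns a reduced-per-gene
## GRanges or NULL.
normalizeCaptureIntervals <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    need <- c("chrom", "start", "end", "gene_id")
    if (!all(need %in% names(x)))
      stop("capture intervals need columns: ", paste(need, collapse = ", "))
    x <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      # BED start is 0-based; IRanges is 1-based closed
      ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
      gene_id = x$gene_id)
  }
  if (!methods::is(x, "GRanges")) stop("unsupported capture interval input")
  if (!"gene_id" %in% names(GenomicRanges::mcols(x)))
    stop("capture intervals must carry a gene_id column")
  parts <- S4Vectors::split(x, GenomicRanges::mcols(x)$gene_id)
  red <- GenomicRanges::reduce(parts)
  out <- unlist(red, use.names = FALSE)
  GenomicRanges::mcols(out)$gene_id <- rep(names(red), lengths(red))
  out
}

## 0-based half-open (start, end) matrix for one gene, or NULL when absent.
intervalsForGene <- function(gr, geneId) {
  if (is.null(gr) || length(gr) == 0L) return(NULL)
  sel <- gr[GenomicRanges::mcols(gr)$gene_id == geneId]
  if (length(sel) == 0L) return(NULL)
  cbind(start = GenomicRanges::start(sel) - 1, end = GenomicRanges::end(sel))
}

#' Read and write panel tables
#'
#' Tab-separated panel files with columns \code{gene_id}, \code{chrom},
#' \code{strand}, \code{tss}, \code{gene_length}, \code{k} (plus the derived
#' \code{tss_excluded} and \code{included} flags when written by
#' \code{writePanel}). Coordinates are 0-based.
#'
#' @param path file path.
#' @return \code{readPanelTable}: a data.frame.
#' @export
readPanelTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readPanelTable
#' @param panel a [GenePanel]
#' @export
writePanel <- function(panel, path) {
  utils::write.table(panel@genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read capture geometry from a BED file
#'
#' Four-column BED (chrom, start, end, name) where the name field carries the
#' gene id. Start coordinates stay 0-based internally.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, gene_id.
#' @export
readCaptureBed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED file must have at least 4 columns")
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             gene_id = bed[[4]], stringsAsFactors = FALSE)
}
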