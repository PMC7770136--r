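## Windowed heterozygosity and pairwise nucleotide mismatch in
## non-overlapping genome tiles (default 100 kb).

#' Tile the genome into non-overlapping windows
#'
#' @param chromLengths named chromosome lengths in bp, or a
#'   [GenotypeCohort] with seqlengths.
#' @param windowSize window span in bp (default 100 kb). Windows tile each
#'   chromosome without overlap; the last window of a chromosome may be
#'   shorter.
#' @return A [GenomicRanges::GRanges] of windows with a logical `complete`
#'   metadata column (`width == windowSize`).
#' @export
genomeWindows <- function(chromLengths, windowSize = 1e5) {
  if (is(chromLengths, "GenotypeCohort"))
    chromLengths <- chromLengths(chromLengths)
  stopifnot(length(chromLengths) > 0, windowSize > 0)
  tiles <- tileGenome(chromLengths, tilewidth = windowSize,
                      cut.last.tile.in.chrom = TRUE)
  tiles$complete <- width(tiles) == windowSize
  tiles
}

## site -> window index (positions are width-1 ranges)
.windowIndex <- function(x, windows) {
  findOverlaps(rowRanges(x), windows, select = "first")
}

#' Per-individual windowed heterozygosity
#'
#' In each window, `He` is 100 times the number of heterozygous genotype
#' calls divided by the window span in bp (a percentage per bp; missing
#' genotypes contribute nothing). The genome-wide value per individual is
#' the mean over complete windows.
#'
#' @param x a [GenotypeCohort] (typically after filtering).
#' @param windowSize window span in bp.
#' @param completeOnly use only complete windows for the genome-wide mean.
#' @return A list with `windows` (the tiling, a `GRanges`), `perWindow`
#'   (windows x samples matrix of He in %), and `genomeWide` (named
#'   numeric of per-individual He in %).
#' @examples
#' sim <- simulateCohort(simConfig(nSamples = 4, targetFroh = 0,
#'   chromosomes = c(chr1 = 2e6), effectCounts = c(synonymous = 0),
#'   seed = 9))
#' windowedHeterozygosity(sim$cohort)$genomeWide
#' @export
windowedHeterozygosity <- function(x, windowSize = 1e5, completeOnly = TRUE) {
  stopifnot(is(x, "GenotypeCohort"))
  windows <- genomeWindows(chromLengths(x), windowSize)
  if (!length(windows)) stop("no windows: check seqlengths")
  wi <- .windowIndex(x, windows)
  het <- genotypes(x) == 1L
  het[is.na(het)] <- FALSE
  counts <- rowsum(het + 0, group = wi, reorder = TRUE)
  perWindow <- matrix(0, length(windows), ncol(x),
                      dimnames = list(NULL, colnames(x)))
  perWindow[as.integer(rownames(counts)), ] <- counts
  perWindow <- 100 * perWindow / width(windows)
  use <- if (completeOnly) windows$complete else rep(TRUE, length(windows))
  list(windows = windows, perWindow = perWindow,
       genomeWide = colMeans(perWindow[use, , drop = FALSE]))
}

#' Pairwise nucleotide mismatch between two individuals
#'
#' Per-site distance is `|dosage_i - dosage_j| / 2` (opposite homozygotes
#' 1, het vs hom 0.5, identical 0) under the default `"dosage"`
#' convention, or the expected allele difference of randomly drawn alleles
#' (`"allele"`: het vs het scores 0.5 instead of 0). Window mismatch is
#' 100 times the summed distance over the window span; the pair value is
#' the mean over complete windows.
#'
#' @param x a [GenotypeCohort].
#' @param i,j sample names or indices.
#' @param windowSize window span in bp.
#' @param convention `"dosage"` (default) or `"allele"`.
#' @param completeOnly use only complete windows for the pair mean.
#' @return A list with `windows`, `perWindow` (numeric vector, %), and
#'   `pairMean` (%).
#' @export
pairwiseMismatch <- function(x, i, j, windowSize = 1e5,
                             convention = c("dosage", "allele"),
                             completeOnly = TRUE) {
  stopifnot(is(x, "GenotypeCohort"))
  convention <- match.arg(convention)
  gi <- genotypes(x)[, i]
  gj <- genotypes(x)[, j]
  if (identical(i, j)) {
    warning("identical sample supplied twice; mismatch is 0")
  }
  d <- if (convention == "dosage") {
    abs(gi - gj) / 2
  } else {
    pi <- gi / 2; pj <- gj / 2
    pi * (1 - pj) + pj * (1 - pi)
  }
  d[is.na(d)] <- 0
  windows <- genomeWindows(chromLengths(x), windowSize)
  wi <- .windowIndex(x, windows)
  sums <- rowsum(d, group = wi, reorder = TRUE)
  perWindow <- numeric(length(windows))
  perWindow[as.integer(rownames(sums))] <- sums
  perWindow <- 100 * perWindow / width(windows)
  use <- if (completeOnly) windows$complete else rep(TRUE, length(windows))
  list(windows = windows, perWindow = perWindow,
       pairMean = mean(perWindow[use]))
}

#' Mean pairwise mismatch within each group
#'
#' Convenience wrapper: [pairwiseMismatch()] for every within-group pair
#' of non-outgroup individuals.
#'
#' @inheritParams pairwiseMismatch
#' @param x a [GenotypeCohort].
#' @return data.frame with `group`, `id1`, `id2`, `mismatch_pct`.
#' @export
groupMismatch <- function(x, windowSize = 1e5,
                          convention = c("dosage", "allele")) {
  convention <- match.arg(convention)
  grp <- sampleGroups(x)
  keep <- !isOutgroup(x)
  out <- list()
  for (g in unique(grp[keep])) {
    ids <- colnames(x)[keep & grp == g]
    if (length(ids) < 2) next
    prs <- combn(ids, 2)
    for (k in seq_len(ncol(prs))) {
      pm <- pairwiseMismatch(x, prs[1, k], prs[2, k],
                             windowSize = windowSize,
                             convention = convention)
      out[[length(out) + 1L]] <- data.frame(
        group = g, id1 = prs[1, k], id2 = prs[2, k],
        mismatch_pct = pm$pairMean, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(0), id1 = character(0),
                      id2 = character(0), mismatch_pct = numeric(0)))
  do.call(rbind, out)
}
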