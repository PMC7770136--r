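## Sliding-window consensus scan for runs of homozygosity (ROH), the
## genomic inbreeding coefficient F_ROH, and ROH length-based generation
## dating.

#' Per-SNP hit fractions from the sliding-window homozygosity scan
#'
#' Slides windows of `windowSnps` consecutive SNPs along a chromosome; a
#' window passes when it contains at most `maxHetPerWindow` heterozygous
#' and at most `maxMissingPerWindow` missing calls. Each SNP's hit
#' fraction is the proportion of windows covering it that pass; SNPs near
#' chromosome ends use only the windows that exist. With fewer SNPs than
#' `windowSnps` on a chromosome no window exists and all hit fractions are
#' zero.
#'
#' @param het logical vector: is the call heterozygous (missing calls
#'   `FALSE`).
#' @param missing logical vector: is the call missing.
#' @param params a [rohScanParams()].
#' @return Numeric vector of per-SNP hit fractions in `[0, 1]`.
#' @export
scoreSnps <- function(het, missing = rep(FALSE, length(het)),
                      params = rohScanParams()) {
  n <- length(het)
  stopifnot(length(missing) == n)
  w <- params$windowSnps
  if (n < w) return(numeric(n))
  csHet <- c(0, cumsum(het))
  csMis <- c(0, cumsum(missing))
  s <- seq_len(n - w + 1L)
  pass <- (csHet[s + w] - csHet[s]) <= params$maxHetPerWindow &
          (csMis[s + w] - csMis[s]) <= params$maxMissingPerWindow
  csPass <- c(0, cumsum(pass))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n - w + 1L)
  (csPass[hi + 1L] - csPass[lo]) / (hi - lo + 1L)
}

#' Call ROH segments from per-SNP hit fractions
#'
#' Maximal runs of consecutive SNPs whose hit fraction is at least
#' `hitFractionThreshold` become candidate segments; a candidate is
#' emitted when its length (first to last contributing SNP position,
#' inclusive) is at least `minLengthBp`, it contains at least
#' `minSnpsPerSegment` SNPs, and its SNP density is at least one SNP per
#' `minDensityBpPerSnp` bp.
#'
#' @param hit per-SNP hit fractions from [scoreSnps()].
#' @param pos sorted 1-based SNP positions (same length).
#' @param het logical heterozygosity per SNP, used to report each
#'   segment's residual het count.
#' @param params a [rohScanParams()].
#' @return data.frame with `start`, `end`, `length`, `nSnps`, `nHet` and
#'   `class` (`"short"` or `"long"`); zero rows when nothing passes.
#' @export
callRohSegments <- function(hit, pos, het = rep(FALSE, length(hit)),
                            params = rohScanParams()) {
  n <- length(hit)
  stopifnot(length(pos) == n, !is.unsorted(pos))
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), nSnps = integer(0),
                      nHet = integer(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  ok <- hit >= params$hitFractionThreshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(empty)
  out <- lapply(runs, function(k) {
    i1 <- starts[k]; i2 <- ends[k]
    len <- pos[i2] - pos[i1] + 1L
    nSnps <- i2 - i1 + 1L
    if (len < params$minLengthBp) return(NULL)
    if (nSnps < params$minSnpsPerSegment) return(NULL)
    if (len / nSnps > params$minDensityBpPerSnp) return(NULL)
    data.frame(start = pos[i1], end = pos[i2], length = len,
               nSnps = nSnps, nHet = sum(het[i1:i2]),
               class = if (len > params$longThresholdBp) "long" else "short",
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect ROH for every individual in a cohort
#'
#' Runs [scoreSnps()] and [callRohSegments()] per individual and
#' chromosome on the cohort's SNPs.
#'
#' @param x a [GenotypeCohort] (filtered; outgroups are skipped).
#' @param params a [rohScanParams()].
#' @param includeOutgroups also scan outgroup samples.
#' @return A [GenomicRanges::GRanges] of segments with metadata columns
#'   `sample`, `nSnps`, `nHet`, `class`.
#' @export
callRoh <- function(x, params = rohScanParams(), includeOutgroups = FALSE) {
  stopifnot(is(x, "GenotypeCohort"))
  if (params$maxMissingPerWindow >= params$windowSnps)
    message("note: maxMissingPerWindow (", params$maxMissingPerWindow,
            ") >= windowSnps (", params$windowSnps,
            "); the missing-call gate cannot fire")
  gt <- genotypes(x)
  chromv <- as.character(seqnames(x))
  posv <- start(rowRanges(x))
  ids <- colnames(x)[if (includeOutgroups) TRUE else !isOutgroup(x)]
  segs <- list()
  for (chr in unique(chromv)) {
    sel <- which(chromv == chr)
    sel <- sel[order(posv[sel])]
    pos <- posv[sel]
    for (s in ids) {
      g <- gt[sel, s]
      het <- !is.na(g) & g == 1L
      mis <- is.na(g)
      hit <- scoreSnps(het, mis, params)
      df <- callRohSegments(hit, pos, het, params)
      if (nrow(df))
        segs[[length(segs) + 1L]] <- GRanges(
          chr, IRanges(df$start, df$end), sample = s, nSnps = df$nSnps,
          nHet = df$nHet, class = df$class, seqinfo = seqinfo(x))
    }
  }
  if (!length(segs))
    return(GRanges(sample = character(0), nSnps = integer(0),
                   nHet = integer(0), class = character(0),
                   seqinfo = seqinfo(x)))
  sort(do.call(c, segs), ignore.strand = TRUE)
}

#' Genomic inbreeding coefficient F_ROH
#'
#' `F_ROH` is the total ROH length within an individual divided by the
#' genome length, partitioned exactly (in bp) into a short component
#' (segments up to the long threshold) and a long component
#' (`F_ROH_1Mb`, segments beyond it). Overlapping segments for an
#' individual are merged with a warning before summing.
#'
#' @param segments `GRanges` from [callRoh()] (with `sample` and `class`
#'   metadata columns).
#' @param genomeLength genome length in bp (sum of autosome lengths), or a
#'   [GenotypeCohort] whose seqlengths are summed.
#' @param samples optional character vector so individuals without any
#'   segment are reported with `fRoh = 0`.
#' @return data.frame per individual: `sample`, `fRoh`, `fRohShort`,
#'   `fRohLong`, `nSegments` (fractions, not %).
#' @export
froh <- function(segments, genomeLength, samples = NULL) {
  if (is(genomeLength, "GenotypeCohort"))
    genomeLength <- sum(as.numeric(chromLengths(genomeLength)))
  stopifnot(is.numeric(genomeLength), genomeLength > 0)
  samples <- samples %||% unique(segments$sample)
  res <- data.frame(sample = samples, fRoh = 0, fRohShort = 0,
                    fRohLong = 0, nSegments = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(samples)) {
    gs <- segments[segments$sample == samples[k]]
    if (!length(gs)) next
    merged <- reduce(gs, min.gapwidth = 0L)
    if (length(merged) != length(gs)) {
      warning("overlapping segments merged for sample ", samples[k])
      merged$class <- ifelse(width(merged) > 1e6, "long", "short")
      gs <- merged
      gs$sample <- samples[k]
    }
    lens <- as.numeric(width(gs))
    res$fRoh[k] <- sum(lens) / genomeLength
    res$fRohLong[k] <- sum(lens[gs$class == "long"]) / genomeLength
    res$fRohShort[k] <- sum(lens[gs$class == "short"]) / genomeLength
    res$nSegments[k] <- length(gs)
  }
  res
}

#' Date an ROH by its genetic length
#'
#' The expected age of the common ancestor of an autozygous segment of
#' genetic length `L` centimorgans is `g = 100 / (2 * L)` generations, so
#' a 1-cM (about 1-Mb at the default 1 cM/Mb) ROH traces back roughly 50
#' generations.
#'
#' @param lengthCm segment length in centimorgans (positive).
#' @return Generations `g`.
#' @examples
#' generationsFromLength(1)    # 50
#' generationsFromLength(50)   # 1
#' @export
generationsFromLength <- function(lengthCm) {
  if (any(!is.finite(lengthCm)) || any(lengthCm <= 0))
    stop("lengthCm must be positive and finite")
  100 / (2 * lengthCm)
}

#' Convert physical segment length to centimorgans
#'
#' @param lengthBp length in bp.
#' @param cmPerMb genetic map density (default 1 cM per Mb).
#' @return Length in centimorgans.
#' @export
bpToCm <- function(lengthBp, cmPerMb = 1) lengthBp / 1e6 * cmPerMb

#' Fractions of sites inside short ROH, long ROH and outside
#'
#' @param sites a `GRanges` of site positions (width 1), or a data.frame
#'   with `chrom` and `pos`.
#' @param segments `GRanges` of one individual's ROH with a `class`
#'   metadata column.
#' @return Named numeric `c(short=, long=, outside=)` summing to 1.
#' @export
overlapFractions <- function(sites, segments) {
  if (is.data.frame(sites))
    sites <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  if (!length(sites)) stop("no sites supplied")
  inShort <- overlapsAny(sites, segments[segments$class == "short"])
  inLong <- overlapsAny(sites, segments[segments$class == "long"])
  ## a site in both (nested/adjacent segments) counts toward long
  short <- sum(inShort & !inLong)
  long <- sum(inLong)
  n <- length(sites)
  c(short = short / n, long = long / n, outside = (n - short - long) / n)
}
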