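## Hard-filter cascade yielding the analysis-ready biallelic autosomal
## SNP set.

.isAutosomeName <- function(x) !toupper(sub("^chr", "", x, ignore.case = TRUE)) %in% c("X", "Y")

## rule order for the first-firing tally (structural rules first, then
## site QC, then genotype-derived rules)
.FILTER_RULES <- c("not_autosome", "not_biallelic_snv", "excluded_region",
                   "QD", "FS", "MQ", "ReadPosRankSum", "SB", "QUAL",
                   "missingness", "MAF")

#' Apply the hard-filter cascade to a cohort
#'
#' A site is removed when any rule fires: not on an autosome, not a
#' biallelic SNV, inside an excluded region, `QD < qdMin`, `FS > fsMax`,
#' `MQ < mqMin`, `ReadPosRankSum < rprsMin`, `SB >= sbMax`,
#' `QUAL < qualMin`, genotype missingness above `maxMissing`, or
#' minor-allele frequency below `minMaf`. Genotypes with depth below
#' `dpMin` are set missing before missingness and allele frequency are
#' computed; both use all samples in the cohort as denominator. A QC rule
#' whose INFO annotation is absent (`NA`) at a site is skipped for that
#' site, with a message summarizing how often. The removal tally assigns
#' each removed site to the first rule that fired, in the fixed order
#' `r paste(.FILTER_RULES, collapse = ", ")`. If the verbatim `SB >= sbMax`
#' criterion removes more than half of all sites a warning is raised,
#' since annotated strand-bias values almost always exceed -1.0.
#'
#' @param x a [GenotypeCohort].
#' @param config a [filterConfig()].
#' @param quiet suppress informational messages.
#' @return A list with `cohort` (retained sites, with low-depth genotypes
#'   masked), `tally` (named removals per first-firing rule plus
#'   `retained`), and `maskedGenotypes` (count of genotypes set missing by
#'   the depth mask).
#' @examples
#' sim <- simulateCohort(simConfig(nSamples = 4,
#'   chromosomes = c(chr1 = 1e6), effectCounts = c(synonymous = 10),
#'   seed = 3))
#' res <- applySiteFilters(sim$cohort, filterConfig())
#' res$tally
#' @export
applySiteFilters <- function(x, config = filterConfig(), quiet = FALSE) {
  stopifnot(is(x, "GenotypeCohort"), inherits(config, "FilterConfig"))
  gt <- genotypes(x)
  dp <- readDepth(x)
  masked <- 0L
  if (!is.null(dp)) {
    low <- !is.na(dp) & dp < config$dpMin & !is.na(gt)
    masked <- sum(low)
    gt[low] <- NA_integer_
    assay(x, "GT") <- gt
  }
  n <- nrow(x)
  rd <- rowData(x)
  chromv <- as.character(seqnames(x))
  autosomes <- config$autosomes %||%
    seqlevels(x)[.isAutosomeName(seqlevels(x))]

  nonMissing <- rowSums(!is.na(gt))
  missFrac <- 1 - nonMissing / ncol(gt)
  afAlt <- rowSums(gt, na.rm = TRUE) / (2 * pmax(nonMissing, 1L))
  maf <- pmin(afAlt, 1 - afAlt)

  qcRule <- function(v, fire) {
    out <- !is.na(v) & fire(v)
    skipped <- sum(is.na(v))
    attr(out, "skipped") <- skipped
    out
  }
  inBed <- rep(FALSE, n)
  if (!is.null(config$excludeRegions))
    inBed <- overlapsAny(rowRanges(x), config$excludeRegions)

  fires <- list(
    not_autosome = !chromv %in% autosomes,
    not_biallelic_snv = grepl(",", rd$ALT) | nchar(rd$REF) != 1L |
      nchar(rd$ALT) != 1L,
    excluded_region = inBed,
    QD = qcRule(rd$QD, function(v) v < config$qdMin),
    FS = qcRule(rd$FS, function(v) v > config$fsMax),
    MQ = qcRule(rd$MQ, function(v) v < config$mqMin),
    ReadPosRankSum = qcRule(rd$ReadPosRankSum,
                            function(v) v < config$rprsMin),
    SB = if ("SB" %in% colnames(rd)) qcRule(rd$SB, function(v) v >= config$sbMax)
         else structure(rep(FALSE, n), skipped = n),
    QUAL = qcRule(rd$QUAL, function(v) v < config$qualMin),
    missingness = missFrac > config$maxMissing,
    MAF = maf < config$minMaf
  )
  fires <- fires[.FILTER_RULES]

  firstRule <- integer(n)
  for (r in seq_along(fires)) {
    f <- as.logical(fires[[r]])
    firstRule[firstRule == 0L & f] <- r
  }
  tally <- tabulate(firstRule, nbins = length(fires))
  names(tally) <- .FILTER_RULES
  tally <- c(tally, retained = sum(firstRule == 0L))

  skipped <- vapply(fires, function(f) attr(f, "skipped") %||% 0L, numeric(1))
  if (!quiet && any(skipped > 0))
    message("INFO annotations absent (rule skipped per site): ",
            paste0(names(skipped)[skipped > 0], "=",
                   skipped[skipped > 0], collapse = ", "))
  if (tally[["SB"]] > n / 2)
    warning("the verbatim SB >= ", config$sbMax, " criterion removed ",
            tally[["SB"]], "/", n, " sites; this threshold removes nearly ",
            "every annotated site and may warrant a config override")

  list(cohort = x[firstRule == 0L, ], tally = tally,
       maskedGenotypes = masked)
}

#' Remove sites overlapping excluded regions
#'
#' Excluded regions (e.g. CpG islands) are given as a BED file (0-based
#' half-open) or a 1-based [GenomicRanges::GRanges]; a site at 1-based
#' position `pos` is removed when `pos - 1` falls inside any BED interval.
#'
#' @param x a [GenotypeCohort].
#' @param regions a `GRanges` or a BED file path (empty input keeps all
#'   sites). Malformed BED lines raise an error naming the line.
#' @return The cohort restricted to sites outside the regions.
#' @export
excludeRegions <- function(x, regions) {
  stopifnot(is(x, "GenotypeCohort"))
  if (is.character(regions)) regions <- readBedRegions(regions)
  if (length(regions) == 0) return(x)
  x[!overlapsAny(rowRanges(x), regions), ]
}
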