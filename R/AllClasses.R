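#' GenotypeCohort: samples x biallelic SNV genotypes
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding a cohort of
#' diploid genotypes at SNV sites. The `"GT"` assay stores alternate-allele
#' dosage (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing); the optional `"DP"` assay stores per-genotype
#' read depth. Row ranges carry one width-1 position per site with
#' `REF`/`ALT` alleles, `QUAL` and the per-site QC annotations
#' (`QD`, `FS`, `MQ`, `ReadPosRankSum`, optionally `SB`) plus an optional
#' SnpEff-style `ANN` effect string. Column data carries `sample`, `group`
#' (species or population label) and the logical `outgroup` flag.
#' Chromosome lengths live in the object's [GenomeInfoDb::Seqinfo].
#'
#' @export
setClass("GenotypeCohort", contains = "RangedSummarizedExperiment")

setValidity("GenotypeCohort", function(object) {
  msg <- character()
  if (!"GT" %in% assayNames(object))
    msg <- c(msg, "assay 'GT' (dosage matrix) is required")
  else {
    gt <- assay(object, "GT")
    bad <- !is.na(gt) & !(gt %in% 0:2)
    if (any(bad))
      msg <- c(msg, "GT dosages must be 0, 1, 2 or NA")
  }
  need <- c("REF", "ALT")
  miss <- setdiff(need, colnames(rowData(object)))
  if (length(miss))
    msg <- c(msg, paste0("rowData must contain: ", paste(miss, collapse = ", ")))
  for (col in c("group", "outgroup"))
    if (!col %in% colnames(colData(object)))
      msg <- c(msg, paste0("colData must contain '", col, "'"))
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeCohort
#'
#' @param gt integer matrix of alternate-allele dosages (sites x samples),
#'   values 0/1/2/NA.
#' @param rowRanges [GenomicRanges::GRanges] of site positions (width 1),
#'   with at least `REF` and `ALT` metadata columns; its seqinfo should
#'   carry chromosome lengths.
#' @param colData `DataFrame`/data.frame of per-sample metadata with
#'   columns `group` and `outgroup`; rownames are sample names.
#' @param dp optional integer matrix of per-genotype read depth.
#' @return A [GenotypeCohort] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'   REF = c("A", "C"), ALT = c("G", "T"),
#'   seqinfo = GenomeInfoDb::Seqinfo("chr1", 1e6))
#' gt <- matrix(c(0L, 1L, 2L, 1L), 2, 2,
#'   dimnames = list(NULL, c("s1", "s2")))
#' cd <- S4Vectors::DataFrame(group = "pop1", outgroup = FALSE,
#'   row.names = c("s1", "s2"))
#' GenotypeCohort(gt, gr, cd)
#' @export
GenotypeCohort <- function(gt, rowRanges, colData, dp = NULL) {
  storage.mode(gt) <- "integer"
  assays <- list(GT = gt)
  if (!is.null(dp)) {
    storage.mode(dp) <- "integer"
    assays$DP <- dp
  }
  se <- SummarizedExperiment(assays = assays, rowRanges = rowRanges,
                             colData = as(colData, "DataFrame"))
  new("GenotypeCohort", se)
}

#' @describeIn GenotypeCohort dosage matrix accessor (sites x samples).
#' @param x a `GenotypeCohort`.
#' @export
genotypes <- function(x) assay(x, "GT")

#' @describeIn GenotypeCohort per-genotype read-depth matrix (or NULL).
#' @export
readDepth <- function(x) {
  if ("DP" %in% assayNames(x)) assay(x, "DP") else NULL
}

#' @describeIn GenotypeCohort per-sample group (species/population) labels.
#' @export
sampleGroups <- function(x) setNames(as.character(colData(x)$group), colnames(x))

#' @describeIn GenotypeCohort logical outgroup flags per sample.
#' @export
isOutgroup <- function(x) setNames(colData(x)$outgroup, colnames(x))

#' @describeIn GenotypeCohort named chromosome lengths from the seqinfo.
#' @export
chromLengths <- function(x) seqlengths(x)

setMethod("show", "GenotypeCohort", function(object) {
  callNextMethod()
  og <- sum(colData(object)$outgroup)
  cat("groups:", paste(unique(colData(object)$group), collapse = ", "), "\n")
  cat("outgroup samples:", og, "\n")
})

## ---------------------------------------------------------------------------

#' TruthSet: planted ground truth of a synthetic cohort
#'
#' Records everything [simulateCohort()] planted, for recovery testing:
#' per-individual autozygous (ROH) intervals and true autozygous fraction,
#' pairwise relationships, per-site effect class and true ancestral allele,
#' and per-individual true homozygous-derived load counts.
#'
#' @slot rohIntervals [GenomicRanges::GRanges] of planted autozygous tracts,
#'   with a `sample` metadata column; non-overlapping per individual.
#' @slot trueFroh named numeric, total planted tract length divided by
#'   genome length, exactly, per individual.
#' @slot relationships data.frame with columns `sample_a`, `sample_b`,
#'   `relation`.
#' @slot effects data.frame with columns `chrom`, `pos`, `gene_id`, `class`,
#'   `ancestral_allele`.
#' @slot loadCounts data.frame of true per-individual polarized counts:
#'   `sample`, `n_hom_derived_lof`, `n_genes_hom_lof`,
#'   `n_hom_derived_missense`, `n_hom_derived_synonymous`.
#' @slot config the list of generator settings that produced the cohort.
#' @export
setClass("TruthSet", representation(
  rohIntervals = "GRanges",
  trueFroh = "numeric",
  relationships = "data.frame",
  effects = "data.frame",
  loadCounts = "data.frame",
  config = "list"
))

setValidity("TruthSet", function(object) {
  msg <- character()
  if (any(object@trueFroh < 0 | object@trueFroh > 1, na.rm = TRUE))
    msg <- c(msg, "trueFroh must lie in [0, 1]")
  gr <- object@rohIntervals
  if (length(gr)) {
    for (s in unique(gr$sample)) {
      gs <- gr[gr$sample == s]
      if (length(reduce(gs, min.gapwidth = 0L)) != length(gs))
        msg <- c(msg, paste0("planted intervals overlap for sample ", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TruthSet planted ROH intervals.
#' @param x a `TruthSet`.
#' @export
truthRoh <- function(x) x@rohIntervals

#' @describeIn TruthSet named per-individual true autozygous fraction.
#' @export
truthFroh <- function(x) x@trueFroh

#' @describeIn TruthSet planted pairwise relationships.
#' @export
truthRelationships <- function(x) x@relationships

#' @describeIn TruthSet per-site effect classes and true ancestral alleles.
#' @export
truthEffects <- function(x) x@effects

#' @describeIn TruthSet true per-individual homozygous-derived load counts.
#' @export
truthLoad <- function(x) x@loadCounts

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet\n")
  cat("  planted ROH intervals:", length(object@rohIntervals), "\n")
  cat("  individuals with F_ROH truth:", length(object@trueFroh), "\n")
  cat("  relationships:", nrow(object@relationships), "\n")
  cat("  effect sites:", nrow(object@effects), "\n")
})

## ---------------------------------------------------------------------------

#' Hard-filter thresholds for SNV site filtering
#'
#' Defaults follow common GATK hard-filter practice for SNVs: a site is
#' removed when `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
#' `ReadPosRankSum < -8.0`, `SB >= -1.0`, `QUAL < 30`, genotype
#' missingness `> 0.20` or minor-allele frequency `< 0.05`, and when it is
#' not a biallelic SNV, not autosomal, or overlaps an excluded region.
#' Genotypes with `DP < dpMin` are set missing before missingness and
#' allele frequency are computed. The `SB >= -1.0` criterion is applied
#' verbatim; because it fires for essentially any annotated strand-bias
#' value it is logged loudly when it removes more than half of all sites
#' (see [applySiteFilters()]).
#'
#' @param qdMin,fsMax,mqMin,rprsMin,sbMax,qualMin site-level QC thresholds.
#' @param dpMin per-genotype minimum depth; lower-depth calls are masked.
#' @param maxMissing maximum fraction of missing genotypes per site.
#' @param minMaf minimum minor-allele frequency across all samples.
#' @param autosomes character vector of autosome names, or `NULL` to use
#'   every seqlevel whose name is not X or Y (with or without a "chr"
#'   prefix).
#' @param excludeRegions a [GenomicRanges::GRanges] of regions to exclude
#'   (e.g. CpG islands), a path to a BED file, or `NULL`.
#' @return A `FilterConfig` object.
#' @export
filterConfig <- function(qdMin = 2.0, fsMax = 60.0, mqMin = 40.0,
                         rprsMin = -8.0, sbMax = -1.0, dpMin = 3L,
                         qualMin = 30, maxMissing = 0.20, minMaf = 0.05,
                         autosomes = NULL, excludeRegions = NULL) {
  stopifnot(maxMissing >= 0, maxMissing <= 1, minMaf >= 0, minMaf <= 0.5)
  if (is.character(excludeRegions))
    excludeRegions <- readBedRegions(excludeRegions)
  structure(list(qdMin = qdMin, fsMax = fsMax, mqMin = mqMin,
                 rprsMin = rprsMin, sbMax = sbMax, dpMin = as.integer(dpMin),
                 qualMin = qualMin, maxMissing = maxMissing, minMaf = minMaf,
                 autosomes = autosomes, excludeRegions = excludeRegions),
            class = "FilterConfig")
}

#' Parameters of the sliding-window ROH scan
#'
#' Defaults mirror a PLINK-style scan: 20-SNP windows, at most one
#' heterozygous and 50 missing calls per window, at least one SNP per
#' 10 kb, minimum segment length 100 kb, long-ROH threshold 1 Mb, per-SNP
#' hit-fraction threshold 0.05 and at least 25 SNPs per segment. Note that
#' with 20-SNP windows the 50-missing-call gate can never fire; it is kept
#' verbatim for fidelity with the scan it reproduces and a message notes
#' this when scanning.
#'
#' @param windowSnps SNPs per sliding window.
#' @param maxHetPerWindow maximum heterozygous calls for a window to pass.
#' @param maxMissingPerWindow maximum missing calls for a window to pass.
#' @param minDensityBpPerSnp maximum bp per SNP inside a segment
#'   (10000 = at least one SNP per 10 kb).
#' @param minLengthBp minimum segment length in bp.
#' @param longThresholdBp boundary between short and long ROH in bp.
#' @param hitFractionThreshold minimum fraction of passing windows covering
#'   a SNP for it to seed/extend a segment.
#' @param minSnpsPerSegment minimum SNPs per emitted segment.
#' @param cmPerMb genetic-to-physical conversion used by generation dating.
#' @return A `RohScanParams` object.
#' @export
rohScanParams <- function(windowSnps = 20L, maxHetPerWindow = 1L,
                          maxMissingPerWindow = 50L,
                          minDensityBpPerSnp = 10000,
                          minLengthBp = 1e5, longThresholdBp = 1e6,
                          hitFractionThreshold = 0.05,
                          minSnpsPerSegment = 25L, cmPerMb = 1) {
  stopifnot(windowSnps >= 1, minLengthBp > 0,
            longThresholdBp >= minLengthBp, minDensityBpPerSnp > 0,
            hitFractionThreshold >= 0, hitFractionThreshold <= 1,
            cmPerMb > 0)
  structure(list(windowSnps = as.integer(windowSnps),
                 maxHetPerWindow = as.integer(maxHetPerWindow),
                 maxMissingPerWindow = as.integer(maxMissingPerWindow),
                 minDensityBpPerSnp = minDensityBpPerSnp,
                 minLengthBp = minLengthBp,
                 longThresholdBp = longThresholdBp,
                 hitFractionThreshold = hitFractionThreshold,
                 minSnpsPerSegment = as.integer(minSnpsPerSegment),
                 cmPerMb = cmPerMb),
            class = "RohScanParams")
}
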