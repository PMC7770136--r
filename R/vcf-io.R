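## VCF serialization of a GenotypeCohort via VariantAnnotation.

.GT_CODES <- c("0/0" = 0L, "0|0" = 0L,
               "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
               "1/1" = 2L, "1|1" = 2L,
               "./." = NA_integer_, "." = NA_integer_,
               ".|." = NA_integer_)

.INFO_KEYS <- data.frame(
  key = c("QD", "FS", "MQ", "ReadPosRankSum", "SB", "ANN"),
  number = c("1", "1", "1", "1", "1", "."),
  type = c("Float", "Float", "Float", "Float", "Float", "String"),
  desc = c("Variant quality by depth",
           "Phred-scaled strand-bias Fisher p",
           "RMS mapping quality",
           "Rank-sum of read position for alt vs ref",
           "Strand bias",
           "Functional annotation: Allele|Annotation|Impact|Gene"),
  stringsAsFactors = FALSE)

#' Write a GenotypeCohort as VCF 4.2
#'
#' Emits diploid `GT` (and `DP` when present) with the site QC annotations
#' (`QD`, `FS`, `MQ`, `ReadPosRankSum`, optionally `SB`) and SnpEff-style
#' `ANN` strings in INFO, plus contig lines from the object's seqinfo.
#' Output is deterministic for a given object (up to the `fileDate` header
#' line, which records the day of writing).
#'
#' @param x a [GenotypeCohort].
#' @param path output path (plain `.vcf`).
#' @return Invisibly, `path`.
#' @seealso [readCohortVcf()]
#' @export
writeCohortVcf <- function(x, path) {
  stopifnot(is(x, "GenotypeCohort"))
  gt <- genotypes(x)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
  gtStr[is.na(gt)] <- "./."
  rd <- rowData(x)
  keys <- intersect(.INFO_KEYS$key, colnames(rd))
  infoDf <- as(rd[, keys, drop = FALSE], "DataFrame")
  hdrInfo <- .INFO_KEYS[match(keys, .INFO_KEYS$key), ]
  hdr <- VCFHeader(samples = colnames(x))
  genoRows <- c("GT", if (!is.null(readDepth(x))) "DP")
  geno(hdr) <- DataFrame(
    Number = c("1", "1")[seq_along(genoRows)],
    Type = c("String", "Integer")[seq_along(genoRows)],
    Description = c("Genotype", "Read depth")[seq_along(genoRows)],
    row.names = genoRows)
  info(hdr) <- DataFrame(Number = hdrInfo$number, Type = hdrInfo$type,
                         Description = hdrInfo$desc, row.names = keys)
  meta(hdr) <- DataFrameList(
    fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  gr <- granges(rowRanges(x))
  if (is.null(names(gr)))
    names(gr) <- paste0(seqnames(gr), ":", start(gr))
  fixed <- DataFrame(
    REF = DNAStringSet(rd$REF),
    ALT = DNAStringSetList(as.list(rd$ALT)),
    QUAL = if ("QUAL" %in% colnames(rd)) as.numeric(rd$QUAL)
           else rep(NA_real_, nrow(rd)),
    FILTER = rep("PASS", nrow(rd)))
  genoList <- list(GT = gtStr)
  if (!is.null(readDepth(x))) genoList$DP <- readDepth(x)
  vcf <- VCF(rowRanges = gr,
             colData = DataFrame(row.names = colnames(x)),
             exptData = list(header = hdr),
             fixed = fixed, info = infoDf,
             geno = do.call(SimpleList, genoList))
  writeVcf(vcf, path)
  invisible(path)
}

#' Read a multi-sample VCF into a GenotypeCohort
#'
#' Parses genotypes to alternate-allele dosage (0/1/2, `NA` for missing),
#' keeps per-genotype `DP` when present, and lifts `QUAL` plus the INFO
#' keys `QD`, `FS`, `MQ`, `ReadPosRankSum`, `SB` and `ANN` into the row
#' data (absent keys become `NA`). Genotypes involving a second alternate
#' allele are counted by their number of non-reference alleles; such sites
#' are flagged as non-biallelic through their comma-joined `ALT` and
#' removed by [applySiteFilters()].
#'
#' @param path a VCF file (plain or bgzipped).
#' @param sampleData optional data.frame of per-sample metadata with
#'   columns `sample`, `group` and `outgroup` (e.g. the `samples.tsv`
#'   written by [writeCohort()]); unknown samples default to group
#'   `"pop1"`, not outgroup.
#' @param chromLengths optional named vector of chromosome lengths,
#'   overriding any contig lengths in the VCF header.
#' @return A [GenotypeCohort].
#' @export
readCohortVcf <- function(path, sampleData = NULL, chromLengths = NULL) {
  vcf <- readVcf(path)
  gtStr <- geno(vcf)$GT
  gt <- matrix(.GT_CODES[gtStr], nrow(gtStr), ncol(gtStr),
               dimnames = dimnames(gtStr))
  ## genotypes referencing further alt alleles: count non-reference alleles
  odd <- is.na(gt) & !gtStr %in% names(.GT_CODES)
  if (any(odd)) {
    gt[odd] <- vapply(strsplit(gtStr[odd], "[/|]"), function(a) {
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a)) NA_integer_ else sum(a > 0L)
    }, integer(1))
  }
  gr <- granges(rowRanges(vcf))
  mcols(gr) <- NULL
  altList <- alt(vcf)
  rd <- DataFrame(
    REF = as.character(ref(vcf)),
    ALT = unname(vapply(as(altList, "CharacterList"), paste,
                        character(1), collapse = ",")),
    QUAL = qual(vcf))
  iv <- info(vcf)
  for (key in .INFO_KEYS$key) {
    rd[[key]] <- if (key %in% colnames(iv)) {
      v <- iv[[key]]
      if (is(v, "List")) {
        v <- as(v, "CharacterList")
        v <- vapply(v, function(e)
          if (length(e)) paste(e, collapse = "&") else NA_character_,
          character(1))
      }
      unname(v)
    } else {
      if (key == "ANN") NA_character_ else NA_real_
    }
  }
  mcols(gr) <- rd
  if (!is.null(chromLengths)) {
    sl <- chromLengths[seqlevels(gr)]
    names(sl) <- seqlevels(gr)
    seqlengths(gr) <- sl
  }
  sn <- colnames(gtStr)
  cd <- DataFrame(group = rep("pop1", length(sn)),
                  outgroup = rep(FALSE, length(sn)),
                  row.names = sn)
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    i <- match(sn, sampleData$sample)
    hit <- !is.na(i)
    cd$group[hit] <- as.character(sampleData$group[i[hit]])
    cd$outgroup[hit] <- as.logical(sampleData$outgroup[i[hit]])
  }
  dp <- geno(vcf)$DP
  if (!is.null(dp)) storage.mode(dp) <- "integer"
  GenotypeCohort(gt, gr, cd, dp = dp)
}

#' Read a BED3 file of regions to exclude
#'
#' Validates the file (at least three tab- or space-separated fields per
#' line, numeric 0-based half-open coordinates, start < end) and imports
#' it as 1-based [GenomicRanges::GRanges] via `rtracklayer`.
#'
#' @param path a BED file.
#' @return A `GRanges` of the intervals.
#' @export
readBedRegions <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 3 || is.na(s) || is.na(e) || s < 0 || e <= s)
      stop("malformed BED line ", i, " in ", path, ": ", lines[i])
  }
  import(path, format = "BED")
}
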