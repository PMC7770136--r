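# Build a GenotypeCohort directly from matrices, for hand fixtures.
handCohort <- function(gt, pos, chrom = "chr1",
                       chromLens = c(chr1 = 1e6),
                       qual = 500, qd = 25, fs = 1, mq = 60, rprs = 0,
                       sb = NULL, ann = NA_character_,
                       ref = "A", alt = "G",
                       groups = "pop1", outgroup = FALSE, dp = NULL) {
  n <- nrow(gt)
  gr <- GenomicRanges::GRanges(
    rep(chrom, length.out = n), IRanges::IRanges(pos, width = 1L),
    seqinfo = GenomeInfoDb::Seqinfo(names(chromLens), unname(chromLens)))
  rd <- S4Vectors::DataFrame(
    REF = rep(ref, length.out = n), ALT = rep(alt, length.out = n),
    QUAL = rep(qual, length.out = n), QD = rep(qd, length.out = n),
    FS = rep(fs, length.out = n), MQ = rep(mq, length.out = n),
    ReadPosRankSum = rep(rprs, length.out = n),
    ANN = rep(ann, length.out = n))
  if (!is.null(sb)) rd$SB <- rep(sb, length.out = n)
  S4Vectors::mcols(gr) <- rd
  if (is.null(colnames(gt)))
    colnames(gt) <- sprintf("s%02d", seq_len(ncol(gt)))
  cd <- S4Vectors::DataFrame(
    group = rep(groups, length.out = ncol(gt)),
    outgroup = rep(outgroup, length.out = ncol(gt)),
    row.names = colnames(gt))
  GenotypeCohort(gt, gr, cd, dp = dp)
}

# The 12-site hand fixture for the filter cascade: 10 samples; per site
# exactly one rule fails (or none). Expected retention: 5 sites.
#   sites 1-2: QD = 1.9            -> removed (QD)
#   site  3:   QUAL = 10           -> removed (QUAL)
#   site  4:   ALT = "G,T"         -> removed (not_biallelic_snv)
#   site  5:   on chrX             -> removed (not_autosome)
#   site  6:   inside the BED      -> removed (excluded_region)
#   site  7:   3/10 genotypes DP=2 -> removed (missingness, 0.3 > 0.2)
#   sites 8-12: clean              -> retained
filterFixture <- function() {
  nS <- 10L
  # 5 hom-ref + 5 het samples per site: AF = 0.25, no missingness
  gt <- matrix(rep(c(rep(0L, 5), rep(1L, 5)), 12), nrow = 12, byrow = TRUE)
  dp <- matrix(10L, 12, nS)
  dp[7, 1:3] <- 2L
  chrom <- c(rep("chr1", 4), "chrX", rep("chr1", 7))
  pos <- c(10e3, 20e3, 30e3, 40e3, 50e3, 100, 70e3,
           80e3, 90e3, 100e3, 110e3, 120e3)
  x <- handCohort(gt, pos, chrom = chrom,
                  chromLens = c(chr1 = 1e6, chrX = 1e6),
                  qd = c(1.9, 1.9, rep(25, 10)),
                  qual = c(500, 500, 10, rep(500, 9)),
                  alt = c(rep("G", 3), "G,T", rep("G", 8)),
                  dp = dp)
  bed <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 100))
  list(cohort = x, bed = bed)
}
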