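test_that("hit fractions are 1 on homozygous and 0 on heterozygous runs", {
  p <- rohScanParams()
  expect_equal(scoreSnps(rep(FALSE, 60), params = p), rep(1, 60))
  # every 20-SNP window on an all-het chromosome has 20 hets
  expect_equal(scoreSnps(rep(TRUE, 60), params = p), rep(0, 60))
  # short chromosomes have no windows and thus no calls
  expect_equal(scoreSnps(rep(FALSE, 10), params = p), rep(0, 10))
})

test_that("scan equals the exhaustive window-enumeration oracle", {
  params <- rohScanParams(minSnpsPerSegment = 5L, minLengthBp = 2e4)
  # 100-SNP fixture with a single het in the middle
  het <- rep(FALSE, 100); het[50] <- TRUE
  pos <- seq(1000, 1000 + 99 * 1000, by = 1000)
  ora <- rohOracle(het, rep(FALSE, 100), pos, params)
  expect_equal(scoreSnps(het, params = params), ora$hit)
  expect_equal(callRohSegments(ora$hit, pos, het, params), ora$segments)
  # randomized instances, including missingness
  set.seed(77)
  for (k in 1:10) {
    n <- sample(30:200, 1)
    het <- runif(n) < 0.2
    mis <- runif(n) < 0.05
    pos <- sort(sample.int(5e5, n))
    ora <- rohOracle(het, mis, pos, params)
    hit <- scoreSnps(het, mis, params)
    expect_equal(hit, ora$hit)
    expect_equal(callRohSegments(hit, pos, het, params), ora$segments)
  }
})

test_that("segment gates enforce length, SNP count and density", {
  params <- rohScanParams()
  # nothing above threshold
  expect_identical(nrow(callRohSegments(rep(0, 50), seq_len(50) * 1e3,
                                        params = params)), 0L)
  # a 50-kb run fails the 100-kb minimum length
  hit <- rep(1, 50)
  pos <- seq(1, 5e4, length.out = 50)
  expect_identical(nrow(callRohSegments(hit, round(pos),
                                        params = params)), 0L)
  # 30 SNPs spread over 400 kb fail the 1-SNP-per-10-kb density gate
  pos <- round(seq(1, 4e5, length.out = 30))
  expect_identical(nrow(callRohSegments(rep(1, 30), pos,
                                        params = params)), 0L)
  expect_error(callRohSegments(rep(1, 3), c(5, 1, 9)), "sorted")
})

test_that("a planted 2-Mb tract is recovered with high overlap", {
  sim <- simulateCohort(simConfig(nSamples = 2,
    chromosomes = c(chr1 = 1e7), targetFroh = 0.2,
    rohLengthDist = list(family = "fixed", length = 2e6),
    effectCounts = c(synonymous = 0), nOutgroups = 0, seed = 33))
  segs <- callRoh(sim$cohort)
  truth <- truthRoh(sim$truth)
  for (s in c("ind01", "ind02")) {
    tr <- truth[truth$sample == s]
    expect_length(tr, 1L)  # one 2-Mb tract planted
    got <- segs[segs$sample == s]
    ov <- GenomicRanges::intersect(got, tr, ignore.strand = TRUE)
    un <- GenomicRanges::union(got, tr, ignore.strand = TRUE)
    jac <- sum(GenomicRanges::width(ov)) / sum(GenomicRanges::width(un))
    expect_gte(jac, 0.9)
  }
})

test_that("F_ROH partitions exactly into short and long components", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 6e6), width = c(5e6, 5e5)),
    sample = "a", class = c("long", "short"))
  fr <- froh(gr, 1e7)
  expect_equal(fr$fRoh, 0.55)
  expect_equal(fr$fRohLong, 0.5)
  expect_equal(fr$fRohShort, 0.05)
  expect_equal(fr$fRohShort + fr$fRohLong, fr$fRoh)
  # no segments -> zero, via the samples argument
  fr0 <- froh(gr[0], 1e7, samples = "b")
  expect_equal(fr0$fRoh, 0)
  # overlapping segments are merged with a warning
  gr2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 3e6), width = c(5e6, 5e6)),
    sample = "a", class = "long")
  expect_warning(frm <- froh(gr2, 1e7), "merged")
  expect_equal(frm$fRoh, 7999999 / 1e7)  # union [1, 7999999]
})

test_that("raising the het tolerance never shrinks total ROH bp", {
  sim <- simulateCohort(simConfig(nSamples = 3,
    chromosomes = c(chr1 = 5e6), targetFroh = 0.5,
    tractHetErrorRate = 0.02, effectCounts = c(synonymous = 0),
    nOutgroups = 0, seed = 44))
  bp <- vapply(1:3, function(mh) {
    segs <- callRoh(sim$cohort, rohScanParams(maxHetPerWindow = mh))
    sum(as.numeric(GenomicRanges::width(segs)))
  }, numeric(1))
  expect_true(all(diff(bp) >= 0))
})

test_that("generation dating follows g = 100 / (2 L)", {
  expect_identical(generationsFromLength(1), 50)
  expect_identical(generationsFromLength(50), 1)
  expect_identical(generationsFromLength(0.5), 100)
  expect_error(generationsFromLength(0), "positive")
  expect_equal(bpToCm(1e6), 1)
  expect_equal(generationsFromLength(bpToCm(2e6)), 25)
})

test_that("site overlap fractions match a point-in-interval hand count", {
  segs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 1000, 5000), end = c(199, 1999, 6999)),
    sample = "a", class = c("short", "long", "short"))
  # 20 sites: 4 in the short [100,199], 6 in the long [1000,1999],
  # 3 in the short [5000,6999], 7 outside
  pos <- c(100, 150, 199, 120, 1000, 1500, 1999, 1001, 1998, 1200,
           5000, 6000, 6999, 200, 999, 2000, 4999, 7000, 9000, 50)
  sites <- data.frame(chrom = "chr1", pos = pos)
  fr <- overlapFractions(sites, segs)
  expect_equal(unname(fr["short"]), 7 / 20)
  expect_equal(unname(fr["long"]), 6 / 20)
  expect_equal(unname(fr["outside"]), 7 / 20)
  expect_equal(sum(fr), 1)
  # degenerate cases
  expect_equal(unname(overlapFractions(sites, segs[0])["outside"]), 1)
  inLong <- data.frame(chrom = "chr1", pos = c(1000, 1500))
  expect_equal(unname(overlapFractions(inLong, segs)["long"]), 1)
})
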