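test_that("identical configs give identical cohorts and truth", {
  cfg <- simConfig(nSamples = 4, chromosomes = c(chr1 = 1e6),
                   effectCounts = c(LOF = 5, missense = 10,
                                    synonymous = 40),
                   missingRate = 0.01, corruptQcFrac = 0.02, seed = 7)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(genotypes(a$cohort), genotypes(b$cohort))
  expect_identical(SummarizedExperiment::rowData(a$cohort),
                   SummarizedExperiment::rowData(b$cohort))
  expect_identical(truthFroh(a$truth), truthFroh(b$truth))
  expect_identical(truthLoad(a$truth), truthLoad(b$truth))
  fa <- tempfile(fileext = ".vcf"); fb <- tempfile(fileext = ".vcf")
  writeCohortVcf(a$cohort, fa)
  writeCohortVcf(b$cohort, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("planted autozygous fraction is exact", {
  sim <- simulateCohort(simConfig(nSamples = 2,
    chromosomes = c(chr1 = 1e7), targetFroh = 0.5,
    effectCounts = c(LOF = 0, missense = 0, synonymous = 0), seed = 2))
  gr <- truthRoh(sim$truth)
  for (s in c("ind01", "ind02")) {
    gs <- gr[gr$sample == s]
    expect_identical(sum(GenomicRanges::width(gs)), 5000000L)
    # non-overlapping by construction
    expect_length(GenomicRanges::reduce(gs, min.gapwidth = 0L), length(gs))
  }
  expect_equal(unname(truthFroh(sim$truth)), c(0.5, 0.5))
})

test_that("zero heterozygosity rate gives all-homozygous genotypes", {
  sim <- simulateCohort(simConfig(nSamples = 3,
    chromosomes = c(chr1 = 5e5), hetRateTheta = 0, targetFroh = 0,
    effectCounts = c(LOF = 0, missense = 0, synonymous = 0), seed = 3))
  expect_true(all(genotypes(sim$cohort) %in% c(0L, 2L)))
})

test_that("realized heterozygous-call rate matches the planted rate", {
  theta <- 5e-4
  sim <- simulateCohort(simConfig(nSamples = 5,
    chromosomes = c(chr1 = 1e7), snpDensity = 1e-3,
    hetRateTheta = theta, targetFroh = 0,
    effectCounts = c(LOF = 0, missense = 0, synonymous = 0), seed = 1))
  gt <- genotypes(sim$cohort)[, !isOutgroup(sim$cohort)]
  n <- length(gt)
  k <- sum(gt == 1L)
  h <- theta / 1e-3
  se <- sqrt(n * h * (1 - h))  # binomial oracle on the draw count
  expect_lt(abs(k - n * h), 3 * se)
  # per-bp rate lands on theta
  rate <- k / (1e7 * ncol(gt))
  expect_lt(abs(rate - theta) / theta, 0.05)
})

test_that("genotypes follow Hardy-Weinberg proportions outside tracts", {
  sim <- simulateCohort(simConfig(nSamples = 10,
    chromosomes = c(chr1 = 2e6), snpDensity = 1e-2, hetRateTheta = 25e-4,
    targetFroh = 0, effectCounts = c(synonymous = 0), seed = 5))
  gt <- genotypes(sim$cohort)[, !isOutgroup(sim$cohort)]
  # pooled over >= 1e4 sites: hom-alt fraction vs (AF)^2 given HW
  af <- rowMeans(gt) / 2
  expHom <- mean(af^2)
  obsHom <- mean(gt == 2L)
  # E[p^2] over 2n draws overestimates hom-alt by Var term p(1-p)/2n
  corr <- mean(af * (1 - af)) / (2 * ncol(gt) - 1)
  expect_lt(abs(obsHom - (expHom - corr)), 0.01)
})

test_that("gamete dropping yields the pedigree IBD structure", {
  set.seed(41)
  p <- runif(50000, 0.05, 0.95)
  dup <- plantRelationship(p, "duplicate")
  expect_identical(dup[, 1], dup[, 2])
  po <- plantRelationship(p, "parent_offspring")
  expect_identical(sum((po[, 1] == 0 & po[, 2] == 2) |
                       (po[, 1] == 2 & po[, 2] == 0)), 0L)
  expect_error(plantRelationship(p, "cousins"), "unknown relation")
})

test_that("relationship samples carry no planted tracts", {
  rel <- data.frame(sample_a = "ind01", sample_b = "ind02",
                    relation = "full_sib")
  sim <- simulateCohort(simConfig(nSamples = 4,
    chromosomes = c(chr1 = 1e6), targetFroh = 0.5, relationships = rel,
    effectCounts = c(synonymous = 0), seed = 8))
  fr <- truthFroh(sim$truth)
  expect_equal(unname(fr[c("ind01", "ind02")]), c(0, 0))
  expect_gt(fr[["ind03"]], 0.4)
})

test_that("effect injection respects counts and errors when overfull", {
  sim <- simulateCohort(simConfig(nSamples = 3,
    chromosomes = c(chr1 = 1e6),
    effectCounts = c(LOF = 0, missense = 0, synonymous = 100), seed = 4))
  expect_identical(sum(truthEffects(sim$truth)$class == "LOF"), 0L)
  expect_true(all(truthLoad(sim$truth)$n_hom_derived_lof == 0L))
  expect_identical(sum(truthEffects(sim$truth)$class == "synonymous"), 100L)
  expect_error(simulateCohort(simConfig(nSamples = 2,
    chromosomes = c(chr1 = 1e4), snpDensity = 1e-3,
    effectCounts = c(synonymous = 1e5), seed = 1)),
    "effect sites")
})

test_that("infeasible settings are rejected by the config", {
  expect_error(simConfig(targetFroh = 1.2), "targetFroh")
  expect_error(simConfig(hetRateTheta = 6e-4, snpDensity = 1e-3),
               "infeasible")
  expect_error(simConfig(relationships = data.frame(
    sample_a = 1, sample_b = 2, relation = "twin")), "unknown relation")
})
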