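test_that("effect terms map to classes with severity precedence", {
  got <- classifyEffects(c("A|stop_gained|HIGH|g1",
                           "T|synonymous_variant|LOW|g2",
                           "C|missense_variant&splice_donor_variant|HIGH|g3",
                           "G|intron_variant|MODIFIER|g4"))
  expect_identical(got$class, c("LOF", "synonymous", "LOF", "other"))
  expect_identical(got$gene_id, c("g1", "g2", "g3", "g4"))
  expect_warning(bad <- classifyEffects("garbled"), "unparseable")
  expect_identical(bad$class, "other")
})

test_that("polarization needs species-major AND outgroup support", {
  # 5 species samples + 2 outgroups; ref frequency 0.9 at site 1
  gt <- rbind(c(0L, 0L, 0L, 0L, 1L, 0L, 0L),   # outgroups hom-ref
              c(0L, 0L, 0L, 0L, 1L, 2L, 2L),   # outgroups hom-alt
              c(0L, 1L, 1L, 1L, 2L, 0L, 0L))   # species AF exactly 0.5
  x <- handCohort(gt, pos = c(100, 200, 300),
                  groups = c(rep("sp", 5), "outgroup", "outgroup"),
                  outgroup = c(rep(FALSE, 5), TRUE, TRUE))
  pol <- polarizeSites(x, group = "sp")
  expect_identical(pol$status, c("polarized", "unpolarized", "unpolarized"))
  expect_identical(pol$ancestral[1], "ref")
  expect_identical(pol$derived[1], "alt")
  # removing outgroups unpolarizes everything
  x2 <- x[, 1:5]
  expect_warning(pol2 <- polarizeSites(x2, group = "sp"), "no outgroup")
  expect_true(all(pol2$status == "unpolarized"))
})

test_that("per-individual load counting matches a hand fixture", {
  # 104 effect sites for one individual: 4 hom-derived LOF in 3 genes,
  # 100 hom-derived synonymous; a second individual all hom-ancestral
  nSites <- 104
  # ind1 hom-alt everywhere; three hom-ref packmates keep AF(ref) = 0.75
  # so ref is ancestral with the hom-ref outgroup
  gt <- cbind(ind1 = rep(2L, nSites), a2 = 0L, a3 = 0L, a4 = 0L, og = 0L)
  ann <- c(sprintf("G|stop_gained|HIGH|gene%d", c(1, 1, 2, 3)),
           rep("G|synonymous_variant|LOW|gene9", 100))
  x <- handCohort(gt, pos = seq_len(nSites) * 100,
                  ann = ann,
                  groups = c(rep("sp", 4), "outgroup"),
                  outgroup = c(rep(FALSE, 4), TRUE))
  eff <- classifyEffects(x)
  pol <- polarizeSites(x, group = "sp")
  expect_true(all(pol$status == "polarized"))
  ld <- individualLoad(x, eff, pol, group = "sp")
  i1 <- ld[ld$sample == "ind1", ]
  expect_identical(i1$n_hom_derived_lof, 4L)
  expect_identical(i1$n_genes_hom_lof, 3L)
  expect_identical(i1$n_hom_derived_synonymous, 100L)
  expect_equal(i1$ratio_lof_syn, 0.04)
  # all-ancestral individuals have zero counts and undefined ratios
  i2 <- ld[ld$sample == "a2", ]
  expect_identical(i2$n_hom_derived_lof + i2$n_hom_derived_missense +
                     i2$n_hom_derived_synonymous, 0L)
  expect_true(is.na(i2$ratio_lof_syn))
})

test_that("load recovered through the VCF equals generator truth exactly", {
  sim <- simulateCohort(simConfig(nSamples = 8,
    chromosomes = c(chr1 = 2e6, chr2 = 2e6),
    effectCounts = c(LOF = 20, missense = 80, synonymous = 400),
    seed = 29))
  path <- tempfile(fileext = ".vcf")
  writeCohortVcf(sim$cohort, path)
  x <- readCohortVcf(path, sampleData = data.frame(
    sample = colnames(sim$cohort), group = sampleGroups(sim$cohort),
    outgroup = isOutgroup(sim$cohort)))
  ld <- cohortLoad(x)
  truth <- truthLoad(sim$truth)
  cols <- c("n_hom_derived_lof", "n_genes_hom_lof",
            "n_hom_derived_missense", "n_hom_derived_synonymous")
  expect_identical(ld[match(truth$sample, ld$sample), cols,
                      drop = FALSE][, cols],
                   truth[, cols])
})

test_that("sidecar effect tables can replace ANN strings", {
  sim <- simulateCohort(simConfig(nSamples = 5,
    chromosomes = c(chr1 = 2e6),
    effectCounts = c(LOF = 10, missense = 20, synonymous = 100),
    seed = 31))
  effTab <- truthEffects(sim$truth)
  viaAnn <- classifyEffects(sim$cohort)
  viaTab <- classifyEffects(sim$cohort, effectsTable = effTab)
  viaTab <- viaTab[order(viaTab$site), ]
  expect_equal(viaAnn$site, viaTab$site)
  expect_identical(viaAnn$class, viaTab$class)
})

test_that("candidate-gene screen recovers group-private planted genes", {
  sim <- simulateCohort(simConfig(nSamples = 8,
    chromosomes = c(chr1 = 2e6),
    effectCounts = c(LOF = 12, missense = 0, synonymous = 60),
    groups = rep(c("spA", "spB"), each = 4), seed = 37))
  ld <- cohortLoad(sim$cohort)
  screen <- candidateGeneScreen(ld)
  truth <- truthLoad(sim$truth)
  # per group, every gene in the screen is carried hom-derived by a member
  eff <- truthEffects(sim$truth)
  expect_true(all(unlist(screen) %in% eff$gene_id[eff$class == "LOF"]))
  # individuals with zero LOF contribute no genes
  zero <- truth$sample[truth$n_hom_derived_lof == 0]
  lg <- attr(ld, "lofGenes")
  expect_true(all(lengths(lg[zero]) == 0))
  # no LOF sites at all -> empty lists
  sim0 <- simulateCohort(simConfig(nSamples = 4,
    chromosomes = c(chr1 = 1e6),
    effectCounts = c(LOF = 0, missense = 0, synonymous = 50), seed = 38))
  expect_true(all(lengths(candidateGeneScreen(cohortLoad(sim0$cohort))) == 0))
})

test_that("ratios are monotone in added hom-derived LOF sites", {
  sim <- simulateCohort(simConfig(nSamples = 5,
    chromosomes = c(chr1 = 2e6),
    effectCounts = c(LOF = 10, missense = 10, synonymous = 100),
    seed = 39))
  x <- sim$cohort
  eff <- classifyEffects(x)
  pol <- polarizeSites(x, group = "pop1", sites = eff$site)
  before <- individualLoad(x, eff, pol, group = "pop1",
                           denominator = "all_synonymous")
  # force one individual hom-derived at every polarized LOF site
  m <- merge(eff[eff$class == "LOF", ],
             pol[pol$status == "polarized", c("site", "derivedDosage")],
             by = "site")
  gt <- genotypes(x)
  gt[m$site, "ind01"] <- m$derivedDosage
  SummarizedExperiment::assay(x, "GT") <- gt
  after <- individualLoad(x, eff, pol, group = "pop1",
                          denominator = "all_synonymous")
  expect_gte(after$ratio_lof_syn[after$sample == "ind01"],
             before$ratio_lof_syn[before$sample == "ind01"])
})
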