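## Synthetic diploid cohorts with planted ground truth.
##
## The generator is first-class, tested code: it emulates the statistical
## structure of a multi-species resequencing cohort (per-site heterozygosity,
## autozygous tracts, pedigree pairs, functional-effect classes, outgroups
## fixed for the ancestral allele) without any coalescent machinery, and
## records everything it plants in a TruthSet.

`%||%` <- function(a, b) if (is.null(a)) b else a

.RELATIONS <- c("parent_offspring", "full_sib", "duplicate", "unrelated")
.LOF_TERMS <- c("stop_gained", "stop_lost", "start_lost",
                "frameshift_variant", "splice_acceptor_variant",
                "splice_donor_variant")

#' Generator settings for a synthetic diploid cohort
#'
#' @param nSamples number of (non-outgroup) individuals.
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param snpDensity expected SNPs per bp.
#' @param hetRateTheta expected heterozygous calls per bp outside autozygous
#'   tracts. The neutral allele-frequency spectrum is a symmetric
#'   `Beta(a, a)` whose shape is calibrated so that the expected per-site
#'   heterozygote probability under Hardy-Weinberg equals
#'   `hetRateTheta / snpDensity`; with `hetRateTheta = 0` every genotype is
#'   homozygous. Requires `hetRateTheta / snpDensity < 0.5`.
#' @param targetFroh fraction of the genome planted autozygous per
#'   individual, in `[0, 1]`. Tracts are forced homozygous.
#' @param rohLengthDist tract-length distribution: a list with a `family`
#'   element (`"lnorm"`, `"gamma"`, `"unif"` or `"fixed"`) plus that
#'   family's parameters (e.g. `meanlog`/`sdlog`, `shape`/`scale`,
#'   `min`/`max`, `length`).
#' @param nOutgroups number of outgroup genomes appended to the cohort.
#' @param outgroupAncestralFidelity probability an outgroup carries the
#'   ancestral allele homozygous at a site (otherwise it is homozygous for
#'   the derived allele).
#' @param effectCounts named counts of planted effect sites for classes
#'   `LOF`, `missense`, `synonymous`.
#' @param derivedHomFrac per-class probability that an individual is
#'   homozygous-derived at an effect site (otherwise homozygous-ancestral).
#' @param geneBlockSize effect sites are grouped into genes in consecutive
#'   blocks of this size (within a chromosome).
#' @param relationships data.frame with columns `sample_a`, `sample_b`,
#'   `relation` (one of `r paste(.RELATIONS, collapse = ", ")`); listed
#'   samples receive gamete-dropped genotypes and no planted tracts.
#' @param groups species/population label per individual (recycled).
#' @param tractHetErrorRate per-SNP probability of an erroneous
#'   heterozygous call inside a planted tract (stresses the ROH caller's
#'   one-het tolerance).
#' @param missingRate per-genotype missingness probability.
#' @param corruptQcFrac fraction of sites whose QC annotations are set to a
#'   failing value, giving the filter module negative cases.
#' @param seed integer seed; fully determines the output.
#' @return A validated `SimConfig` list.
#' @seealso [simulateCohort()]
#' @export
simConfig <- function(nSamples = 10L,
                      chromosomes = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                      snpDensity = 1e-3,
                      hetRateTheta = 4.3e-4,
                      targetFroh = 0.68,
                      rohLengthDist = list(family = "lnorm",
                                           meanlog = log(4e5), sdlog = 0.8),
                      nOutgroups = 2L,
                      outgroupAncestralFidelity = 0.95,
                      effectCounts = c(LOF = 60, missense = 600,
                                       synonymous = 8000),
                      derivedHomFrac = c(LOF = 0.30, missense = 0.35,
                                         synonymous = 0.45),
                      geneBlockSize = 3L,
                      relationships = NULL,
                      groups = "pop1",
                      tractHetErrorRate = 0,
                      missingRate = 0,
                      corruptQcFrac = 0,
                      seed = 1L) {
  stopifnot(nSamples >= 1, length(chromosomes) >= 1, all(chromosomes > 0),
            !is.null(names(chromosomes)), snpDensity > 0,
            hetRateTheta >= 0, nOutgroups >= 0,
            outgroupAncestralFidelity >= 0, outgroupAncestralFidelity <= 1,
            all(effectCounts >= 0), all(derivedHomFrac >= 0),
            all(derivedHomFrac <= 1), geneBlockSize >= 1,
            tractHetErrorRate >= 0, tractHetErrorRate <= 1,
            missingRate >= 0, missingRate < 1,
            corruptQcFrac >= 0, corruptQcFrac <= 1)
  if (targetFroh < 0 || targetFroh > 1)
    stop("targetFroh must lie in [0, 1], got ", targetFroh)
  h <- hetRateTheta / snpDensity
  if (h > 0.5)
    stop("infeasible heterozygosity: hetRateTheta/snpDensity = ", h,
         " but the per-site heterozygote probability cannot exceed 0.5")
  if (!is.list(rohLengthDist) || is.null(rohLengthDist$family))
    stop("rohLengthDist must be a list with a 'family' element")
  if (!is.null(relationships)) {
    relationships <- as.data.frame(relationships)
    stopifnot(all(c("sample_a", "sample_b", "relation") %in%
                    colnames(relationships)))
    bad <- setdiff(relationships$relation, .RELATIONS)
    if (length(bad))
      stop("unknown relation label(s): ", paste(bad, collapse = ", "))
  }
  cfg <- list(nSamples = as.integer(nSamples), chromosomes = chromosomes,
              snpDensity = snpDensity, hetRateTheta = hetRateTheta,
              targetFroh = targetFroh, rohLengthDist = rohLengthDist,
              nOutgroups = as.integer(nOutgroups),
              outgroupAncestralFidelity = outgroupAncestralFidelity,
              effectCounts = effectCounts, derivedHomFrac = derivedHomFrac,
              geneBlockSize = as.integer(geneBlockSize),
              relationships = relationships, groups = groups,
              tractHetErrorRate = tractHetErrorRate,
              missingRate = missingRate, corruptQcFrac = corruptQcFrac,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

## Draw n tract lengths (bp) from the configured family.
.rTractLength <- function(dist, n) {
  switch(dist$family,
    lnorm = rlnorm(n, dist$meanlog, dist$sdlog),
    gamma = rgamma(n, shape = dist$shape,
                   scale = dist$scale %||% (1 / dist$rate)),
    unif  = runif(n, dist$min, dist$max),
    fixed = rep(dist$length, n),
    stop("unknown tract-length family: ", dist$family))
}

## Ordered-uniform placement of non-overlapping tracts summing to exactly
## targetBp on a chromosome of length L. Gaps are an exchangeable
## Dirichlet(1,..,1) split of the residue, which is the distribution of
## gaps under uniform non-overlapping placement.
.placeTracts <- function(L, targetBp, dist) {
  targetBp <- round(targetBp)
  if (targetBp <= 0) return(IRanges())
  if (targetBp > L)
    stop("infeasible target_froh: requested ", targetBp,
         " autozygous bp on a ", L, " bp chromosome")
  lens <- integer(0)
  while (sum(lens) < targetBp)
    lens <- c(lens, pmax(1L, as.integer(round(.rTractLength(dist, 8L)))))
  k <- which(cumsum(as.numeric(lens)) >= targetBp)[1]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (sum(lens) - targetBp)
  if (lens[k] == 0L) lens <- lens[-k]
  nT <- length(lens)
  totalGap <- L - sum(lens)
  w <- rexp(nT + 1)
  gapsF <- w / sum(w) * totalGap
  gaps <- floor(gapsF)
  extra <- as.integer(totalGap - sum(gaps))
  if (extra > 0) {
    give <- order(gapsF - gaps, decreasing = TRUE)[seq_len(extra)]
    gaps[give] <- gaps[give] + 1
  }
  starts <- gaps[1] + 1 + c(0, cumsum(lens[-nT] + gaps[-c(1, nT + 1)]))
  IRanges(start = starts, width = lens)
}

#' Drop gametes for a pair with a known relationship
#'
#' Builds two genotype vectors over sites with the given alternate-allele
#' frequencies so that the pair has the identity-by-descent structure of
#' the stated relationship: `parent_offspring` shares exactly one allele at
#' every site, `full_sib` shares 0/1/2 alleles with probability
#' 1/4, 1/2, 1/4, `duplicate` is a copy, `unrelated` is drawn
#' independently. Marginally each genotype is Hardy-Weinberg at its site
#' frequency.
#'
#' @param freqs numeric vector of alternate-allele frequencies in `[0, 1]`.
#' @param relation one of `"parent_offspring"`, `"full_sib"`,
#'   `"duplicate"`, `"unrelated"`.
#' @return An integer matrix with one column per individual (dosages
#'   0/1/2).
#' @examples
#' set.seed(1)
#' g <- plantRelationship(runif(1000, 0.1, 0.9), "parent_offspring")
#' # opposite homozygotes are impossible for parent and offspring:
#' sum(g[, 1] == 0 & g[, 2] == 2 | g[, 1] == 2 & g[, 2] == 0)
#' @export
plantRelationship <- function(freqs, relation) {
  if (!relation %in% .RELATIONS)
    stop("unknown relation label: ", relation)
  n <- length(freqs)
  draw <- function() rbinom(n, 1L, freqs)
  pick <- function(x, y) ifelse(rbinom(n, 1L, 0.5) == 1L, x, y)
  g <- switch(relation,
    duplicate = {
      gi <- draw() + draw()
      cbind(gi, gi)
    },
    unrelated = cbind(draw() + draw(), draw() + draw()),
    parent_offspring = {
      pa1 <- draw(); pa2 <- draw()
      cbind(pa1 + pa2, pick(pa1, pa2) + draw())
    },
    full_sib = {
      pa1 <- draw(); pa2 <- draw(); pb1 <- draw(); pb2 <- draw()
      cbind(pick(pa1, pa2) + pick(pb1, pb2),
            pick(pa1, pa2) + pick(pb1, pb2))
    })
  storage.mode(g) <- "integer"
  colnames(g) <- NULL
  g
}

## True per-individual polarized load counts, applied to the generator's
## own realized matrices: a site is polarized iff one allele has
## within-group frequency > 0.5 (non-missing, non-outgroup genotypes) and
## at least one outgroup individual is homozygous for it.
.truthLoadCounts <- function(gt, groups, outgroup, effIdx, effClass, effGene) {
  samples <- colnames(gt)[!outgroup]
  res <- data.frame(sample = samples,
                    n_hom_derived_lof = 0L, n_genes_hom_lof = 0L,
                    n_hom_derived_missense = 0L,
                    n_hom_derived_synonymous = 0L,
                    stringsAsFactors = FALSE)
  if (!length(effIdx)) return(res)
  og <- gt[effIdx, outgroup, drop = FALSE]
  lofGenes <- rep(list(character(0)), length(samples))
  names(lofGenes) <- samples
  for (grp in unique(groups[!outgroup])) {
    members <- colnames(gt)[!outgroup & groups == grp]
    gm <- gt[effIdx, members, drop = FALSE]
    afAlt <- rowMeans(gm / 2, na.rm = TRUE)
    candDos <- ifelse(!is.nan(afAlt) & afAlt > 0.5, 2L,
                      ifelse(!is.nan(afAlt) & afAlt < 0.5, 0L, NA_integer_))
    supported <- !is.na(candDos) &
      vapply(seq_along(effIdx), function(i)
        any(og[i, ] == candDos[i], na.rm = TRUE), logical(1))
    derDos <- 2L - candDos
    for (s in members) {
      homDer <- supported & !is.na(gm[, s]) & gm[, s] == derDos
      homDer[is.na(homDer)] <- FALSE
      res$n_hom_derived_lof[res$sample == s] <-
        sum(homDer & effClass == "LOF")
      res$n_hom_derived_missense[res$sample == s] <-
        sum(homDer & effClass == "missense")
      res$n_hom_derived_synonymous[res$sample == s] <-
        sum(homDer & effClass == "synonymous")
      lofGenes[[s]] <- unique(effGene[homDer & effClass == "LOF"])
    }
  }
  res$n_genes_hom_lof <- lengths(lofGenes)[res$sample]
  res
}

#' Simulate a diploid cohort with planted ground truth
#'
#' Generates a multi-sample genotype cohort under the settings of a
#' [simConfig()]: SNP positions are uniform at the configured density;
#' outside planted tracts genotypes are drawn per site from a symmetric
#' Beta allele-frequency spectrum under Hardy-Weinberg; inside planted
#' autozygous tracts all genotypes are homozygous; listed sample pairs are
#' gamete-dropped to their pedigree relationship; designated sites receive
#' functional-effect annotations with genotypes forced homozygous for the
#' derived or ancestral allele; outgroup genomes are homozygous-ancestral
#' with the configured fidelity; and every site carries QC annotations at
#' pass levels (unless corrupted on purpose). Identical configs (including
#' the seed) give identical output.
#'
#' @param config a [simConfig()] object.
#' @return A list with elements `cohort` (a [GenotypeCohort]) and `truth`
#'   (a [TruthSet]).
#' @examples
#' sim <- simulateCohort(simConfig(nSamples = 4,
#'   chromosomes = c(chr1 = 2e6), effectCounts = c(LOF = 5, missense = 10,
#'   synonymous = 50), targetFroh = 0.3, seed = 42))
#' sim$cohort
#' truthFroh(sim$truth)
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  chroms <- config$chromosomes
  nS <- config$nSamples
  nO <- config$nOutgroups
  samples <- sprintf("ind%02d", seq_len(nS))
  outs <- if (nO > 0) sprintf("outg%d", seq_len(nO)) else character(0)
  groups <- rep_len(config$groups, nS)

  rel <- config$relationships
  if (!is.null(rel)) {
    norm <- function(v) if (is.numeric(v)) samples[v] else as.character(v)
    rel$sample_a <- norm(rel$sample_a)
    rel$sample_b <- norm(rel$sample_b)
    ids <- c(rel$sample_a, rel$sample_b)
    if (anyDuplicated(ids))
      stop("a sample may participate in at most one planted relationship")
    if (!all(ids %in% samples))
      stop("relationship samples must be cohort individuals")
  } else {
    rel <- data.frame(sample_a = character(0), sample_b = character(0),
                      relation = character(0), stringsAsFactors = FALSE)
  }
  relSamples <- c(rel$sample_a, rel$sample_b)

  h <- config$hetRateTheta / config$snpDensity
  aShape <- if (h > 0 && h < 0.5) h / (1 - 2 * h) else 0.5

  posL <- list(); chromL <- list(); pL <- list(); gL <- list()
  tractHits <- list()  # per-chrom list of per-sample site indices in tracts
  rohGr <- GRanges(seqinfo = Seqinfo(names(chroms), unname(chroms)))
  plantedBp <- setNames(numeric(nS), samples)

  for (k in seq_along(chroms)) {
    L <- unname(chroms[k])
    n <- rpois(1, config$snpDensity * L)
    n <- max(n, 1L)
    pos <- sort(sample.int(L, min(n, L)))
    n <- length(pos)
    ## at h = 0.5 the calibrated spectrum degenerates to p = 1/2
    p <- if (h >= 0.5) rep(0.5, n) else rbeta(n, aShape, aShape)
    if (h > 0) {
      g <- matrix(rbinom(n * nS, 1L, p) + rbinom(n * nS, 1L, p), n, nS)
    } else {
      g <- 2L * matrix(rbinom(n * nS, 1L, p), n, nS)
    }
    colnames(g) <- samples
    for (r in seq_len(nrow(rel))) {
      gg <- plantRelationship(p, rel$relation[r])
      g[, rel$sample_a[r]] <- gg[, 1]
      g[, rel$sample_b[r]] <- gg[, 2]
    }
    ## autozygous tracts (skipped for relationship samples)
    for (s in setdiff(samples, relSamples)) {
      tr <- .placeTracts(L, config$targetFroh * L, config$rohLengthDist)
      if (length(tr)) {
        inTract <- which(!is.na(findOverlaps(
          IRanges(pos, width = 1L), tr, select = "first")))
        g[inTract, s] <- 2L * rbinom(length(inTract), 1L, p[inTract])
        if (config$tractHetErrorRate > 0) {
          err <- runif(length(inTract)) < config$tractHetErrorRate
          g[inTract[err], s] <- 1L
        }
        rohGr <- c(rohGr, GRanges(names(chroms)[k], tr, sample = s,
                                  seqinfo = seqinfo(rohGr)))
        plantedBp[s] <- plantedBp[s] + sum(width(tr))
      }
    }
    storage.mode(g) <- "integer"
    posL[[k]] <- pos; chromL[[k]] <- rep(names(chroms)[k], n)
    pL[[k]] <- p; gL[[k]] <- g
  }

  pos <- unlist(posL); chrom <- unlist(chromL); p <- unlist(pL)
  g <- do.call(rbind, gL)
  N <- length(pos)

  refIdx <- sample.int(4L, N, replace = TRUE)
  altShift <- sample.int(3L, N, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  refB <- bases[refIdx]
  altB <- bases[(refIdx - 1L + altShift) %% 4L + 1L]

  ## ---- functional effects -------------------------------------------------
  effCounts <- config$effectCounts[config$effectCounts > 0]
  m <- sum(effCounts)
  effIdx <- integer(0); effClass <- character(0); effGene <- character(0)
  ancDosAll <- ifelse(p <= 0.5, 0L, 2L)
  ann <- rep(NA_character_, N)
  if (m > 0) {
    if (m > N)
      stop("requested ", m, " effect sites but only ", N, " sites exist")
    effIdx <- sort(sample.int(N, m))
    effClass <- sample(rep(names(effCounts), effCounts))
    ancRef <- sample(c(TRUE, FALSE), m, replace = TRUE)
    ancDos <- ifelse(ancRef, 0L, 2L)
    derDos <- 2L - ancDos
    ## gene ids: consecutive blocks within a chromosome
    blk <- ave(seq_len(m), chrom[effIdx], FUN = function(i)
      ceiling(seq_along(i) / config$geneBlockSize))
    effGene <- sprintf("gene_%s_%04d", chrom[effIdx], blk)
    dhf <- config$derivedHomFrac[effClass]
    dhf[is.na(dhf)] <- 0
    u <- matrix(runif(m * nS), m, nS)
    gEff <- ifelse(u < dhf, derDos, ancDos)
    storage.mode(gEff) <- "integer"
    g[effIdx, ] <- gEff
    ancDosAll[effIdx] <- ancDos
    term <- character(m)
    term[effClass == "LOF"] <- sample(.LOF_TERMS, sum(effClass == "LOF"),
                                      replace = TRUE)
    term[effClass == "missense"] <- "missense_variant"
    term[effClass == "synonymous"] <- "synonymous_variant"
    impact <- c(LOF = "HIGH", missense = "MODERATE",
                synonymous = "LOW")[effClass]
    ann[effIdx] <- paste(altB[effIdx], term, impact, effGene, sep = "|")
  }

  ## ---- outgroups ----------------------------------------------------------
  if (nO > 0) {
    u <- matrix(runif(N * nO), N, nO)
    gOut <- ifelse(u < config$outgroupAncestralFidelity,
                   ancDosAll, 2L - ancDosAll)
    storage.mode(gOut) <- "integer"
    colnames(gOut) <- outs
    g <- cbind(g, gOut)
  }

  ## ---- missingness --------------------------------------------------------
  if (config$missingRate > 0) {
    drop <- matrix(runif(N * ncol(g)) < config$missingRate, N, ncol(g))
    g[drop] <- NA_integer_
  }

  ## ---- QC annotations at pass levels --------------------------------------
  qualv <- round(runif(N, 100, 1000), 1)
  qd <- round(runif(N, 15, 35), 2)
  fs <- round(runif(N, 0, 10), 3)
  mq <- round(runif(N, 50, 60), 2)
  rprs <- round(rnorm(N, 0, 1), 3)
  rprs <- pmax(pmin(rprs, 7.9), -7.9)
  corrupted <- data.frame(chrom = character(0), pos = integer(0),
                          field = character(0), stringsAsFactors = FALSE)
  if (config$corruptQcFrac > 0) {
    nb <- round(config$corruptQcFrac * N)
    bad <- sample.int(N, nb)
    fld <- sample(c("QD", "FS", "MQ", "ReadPosRankSum", "QUAL"), nb,
                  replace = TRUE)
    qd[bad[fld == "QD"]] <- 1.0
    fs[bad[fld == "FS"]] <- 70.0
    mq[bad[fld == "MQ"]] <- 30.0
    rprs[bad[fld == "ReadPosRankSum"]] <- -9.0
    qualv[bad[fld == "QUAL"]] <- 10
    corrupted <- data.frame(chrom = chrom[bad], pos = pos[bad], field = fld,
                            stringsAsFactors = FALSE)
  }
  dp <- matrix(3L + rpois(N * ncol(g), 9), N, ncol(g),
               dimnames = list(NULL, colnames(g)))

  ## ---- assemble -----------------------------------------------------------
  gr <- GRanges(chrom, IRanges(pos, width = 1L),
                seqinfo = Seqinfo(names(chroms), unname(chroms)))
  mcols(gr) <- DataFrame(REF = refB, ALT = altB, QUAL = qualv, QD = qd,
                         FS = fs, MQ = mq, ReadPosRankSum = rprs, ANN = ann)
  names(gr) <- paste0(chrom, ":", pos)
  rownames(g) <- names(gr); rownames(dp) <- names(gr)
  cd <- DataFrame(group = c(groups, rep("outgroup", nO)),
                  outgroup = c(rep(FALSE, nS), rep(TRUE, nO)),
                  meanDepth = colMeans(dp),
                  row.names = c(samples, outs))
  cohort <- GenotypeCohort(g, gr, cd, dp = dp)

  effects <- data.frame(chrom = chrom[effIdx], pos = pos[effIdx],
                        gene_id = effGene, class = effClass,
                        ancestral_allele = ifelse(ancDosAll[effIdx] == 0L,
                                                  refB[effIdx], altB[effIdx]),
                        stringsAsFactors = FALSE)
  loadCounts <- .truthLoadCounts(g, c(groups, rep("outgroup", nO)),
                                 c(rep(FALSE, nS), rep(TRUE, nO)),
                                 effIdx, effClass, effGene)
  truth <- new("TruthSet",
               rohIntervals = rohGr,
               trueFroh = plantedBp / sum(chroms),
               relationships = rel,
               effects = effects,
               loadCounts = loadCounts,
               config = c(unclass(config), list(corrupted = corrupted)))
  list(cohort = cohort, truth = truth)
}

#' Write a simulated cohort to plain-text files
#'
#' Serializes a [simulateCohort()] result to a directory: `cohort.vcf`
#' (VCF 4.2), `effects.tsv` (chrom, pos, gene_id, class, ancestral_allele),
#' `samples.tsv` (sample, group, outgroup, mean_depth),
#' `chrom_lengths.tsv` and `truth.json`.
#'
#' @param sim a list with `cohort` and `truth`, as returned by
#'   [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "cohort.vcf")
  writeCohortVcf(sim$cohort, vcf)
  eff <- file.path(dir, "effects.tsv")
  write.table(truthEffects(sim$truth), eff, sep = "\t", quote = FALSE,
              row.names = FALSE)
  smp <- file.path(dir, "samples.tsv")
  cd <- colData(sim$cohort)
  write.table(data.frame(sample = rownames(cd), group = cd$group,
                         outgroup = cd$outgroup,
                         mean_depth = cd$meanDepth),
              smp, sep = "\t", quote = FALSE, row.names = FALSE)
  chr <- file.path(dir, "chrom_lengths.tsv")
  sl <- chromLengths(sim$cohort)
  write.table(data.frame(chrom = names(sl), length = unname(sl)),
              chr, sep = "\t", quote = FALSE, row.names = FALSE)
  tj <- file.path(dir, "truth.json")
  gr <- truthRoh(sim$truth)
  write_json(list(
    true_froh = as.list(truthFroh(sim$truth)),
    relationships = truthRelationships(sim$truth),
    roh_intervals = data.frame(chrom = as.character(seqnames(gr)),
                               start = start(gr), end = end(gr),
                               sample = gr$sample),
    load_counts = truthLoad(sim$truth)),
    tj, auto_unbox = TRUE, digits = NA)
  invisible(c(vcf, eff, smp, chr, tj))
}
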