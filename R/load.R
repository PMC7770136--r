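## Effect classification, ancestral polarization against outgroups, and
## per-individual genetic-load statistics.

.LOF_SET <- c("stop_gained", "stop_lost", "start_lost",
              "frameshift_variant", "splice_acceptor_variant",
              "splice_donor_variant")

## severity precedence for multi-effect annotations
.classFromTerms <- function(terms) {
  if (any(terms %in% .LOF_SET)) "LOF"
  else if ("missense_variant" %in% terms) "missense"
  else if ("synonymous_variant" %in% terms) "synonymous"
  else "other"
}

#' Classify variant effects from ANN strings or a sidecar table
#'
#' Maps SnpEff-style annotation terms to the classes used for load
#' statistics: LOF (`r paste(.LOF_SET, collapse = ", ")`), missense
#' (`missense_variant`) and synonymous (`synonymous_variant`); everything
#' else (or an unparseable string, with a warning) is `other`.
#' Multi-effect annotations (terms joined by `&`, or several
#' comma-separated ANN entries) take the most severe class
#' (LOF > missense > synonymous > other).
#'
#' @param x a [GenotypeCohort] with an `ANN` row-data column, or a
#'   character vector of ANN strings.
#' @param effectsTable optional sidecar data.frame (`chrom`, `pos`,
#'   `gene_id`, `class`) used instead of ANN strings; classes other than
#'   LOF/missense/synonymous become `other`.
#' @return data.frame with one row per annotated site: `site` (row index
#'   into `x` when a cohort was given), `chrom`, `pos`, `gene_id`,
#'   `class`.
#' @examples
#' classifyEffects(c("A|stop_gained|HIGH|g1",
#'                   "T|missense_variant&splice_donor_variant|HIGH|g2"))
#' @export
classifyEffects <- function(x, effectsTable = NULL) {
  if (is(x, "GenotypeCohort")) {
    chrom <- as.character(seqnames(x))
    pos <- start(rowRanges(x))
    if (!is.null(effectsTable)) {
      effectsTable <- as.data.frame(effectsTable)
      key <- paste(chrom, pos)
      i <- match(paste(effectsTable$chrom, effectsTable$pos), key)
      keep <- !is.na(i)
      cls <- as.character(effectsTable$class[keep])
      cls[!cls %in% c("LOF", "missense", "synonymous")] <- "other"
      return(data.frame(site = i[keep], chrom = effectsTable$chrom[keep],
                        pos = effectsTable$pos[keep],
                        gene_id = as.character(effectsTable$gene_id[keep]),
                        class = cls, stringsAsFactors = FALSE))
    }
    ann <- rowData(x)$ANN
    if (is.null(ann))
      stop("cohort has no ANN annotations and no effectsTable was given")
    idx <- which(!is.na(ann))
    parsed <- .parseAnn(ann[idx])
    return(data.frame(site = idx, chrom = chrom[idx], pos = pos[idx],
                      gene_id = parsed$gene, class = parsed$class,
                      stringsAsFactors = FALSE))
  }
  parsed <- .parseAnn(x)
  data.frame(site = seq_along(x), chrom = NA_character_, pos = NA_integer_,
             gene_id = parsed$gene, class = parsed$class,
             stringsAsFactors = FALSE)
}

.parseAnn <- function(ann) {
  cls <- character(length(ann))
  gene <- rep(NA_character_, length(ann))
  bad <- 0L
  for (k in seq_along(ann)) {
    entries <- strsplit(ann[k], ",", fixed = TRUE)[[1]]
    fields <- strsplit(entries, "|", fixed = TRUE)
    terms <- unlist(lapply(fields, function(f)
      if (length(f) >= 2) strsplit(f[2], "&", fixed = TRUE)[[1]] else NA))
    if (anyNA(terms) || !length(terms)) {
      bad <- bad + 1L
      cls[k] <- "other"
      next
    }
    cls[k] <- .classFromTerms(terms)
    g <- vapply(fields, function(f)
      if (length(f) >= 4) f[4] else NA_character_, character(1))
    gene[k] <- g[!is.na(g)][1]
  }
  if (bad > 0)
    warning(bad, " unparseable ANN string(s) classed as 'other'")
  list(class = cls, gene = gene)
}

#' Polarize sites into ancestral and derived alleles
#'
#' For one species group, an allele is called ancestral iff its frequency
#' among the group's non-missing genotypes is strictly above 0.5 AND at
#' least one outgroup individual is homozygous for it; otherwise the site
#' is `unpolarized` and excluded from load counts. Note a site where the
#' within-species major allele is contradicted by all outgroups is
#' unpolarized, as is an exact 50/50 frequency.
#'
#' @param x a [GenotypeCohort] containing the group members and at least
#'   one outgroup sample.
#' @param group the species/population label to polarize (default: the
#'   single non-outgroup group present).
#' @param sites optional integer vector of site (row) indices to
#'   polarize; defaults to all sites.
#' @return data.frame with `site`, `status` (`"polarized"`/
#'   `"unpolarized"`), `ancestral` and `derived` (`"ref"`/`"alt"`, NA
#'   when unpolarized), and `derivedDosage` (the GT dosage value that is
#'   homozygous-derived).
#' @export
polarizeSites <- function(x, group = NULL, sites = NULL) {
  stopifnot(is(x, "GenotypeCohort"))
  og <- isOutgroup(x)
  if (!any(og))
    warning("no outgroup samples: every site is unpolarized")
  grp <- sampleGroups(x)
  if (is.null(group)) {
    gg <- unique(grp[!og])
    if (length(gg) != 1)
      stop("multiple groups present; specify 'group'")
    group <- gg
  }
  members <- colnames(x)[!og & grp == group]
  if (!length(members)) stop("no members of group ", group)
  sites <- sites %||% seq_len(nrow(x))
  gm <- genotypes(x)[sites, members, drop = FALSE]
  goMat <- genotypes(x)[sites, og, drop = FALSE]
  afAlt <- rowMeans(gm / 2, na.rm = TRUE)
  candDos <- ifelse(!is.nan(afAlt) & afAlt > 0.5, 2L,
                    ifelse(!is.nan(afAlt) & afAlt < 0.5, 0L, NA_integer_))
  supported <- !is.na(candDos) & rowSums(goMat == candDos, na.rm = TRUE) > 0
  status <- ifelse(supported, "polarized", "unpolarized")
  ancestral <- ifelse(supported, ifelse(candDos == 0L, "ref", "alt"),
                      NA_character_)
  derived <- ifelse(supported, ifelse(candDos == 0L, "alt", "ref"),
                    NA_character_)
  data.frame(site = sites, status = status, ancestral = ancestral,
             derived = derived,
             derivedDosage = ifelse(supported, 2L - candDos, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Per-individual genetic-load summary
#'
#' For each member of the group, counts polarized sites at which the
#' individual is homozygous for the derived allele, split by effect
#' class: `n_hom_derived_lof` (plus `n_genes_hom_lof`, the number of
#' distinct genes carrying at least one such LOF), `n_hom_derived_missense`
#' and `n_hom_derived_synonymous`. Ratios `ratio_lof_syn` and
#' `ratio_mis_syn` divide the LOF and missense counts by the synonymous
#' denominator: by default the individual's homozygous-derived synonymous
#' count; `denominator = "all_synonymous"` divides by the number of
#' polarized synonymous sites instead. Ratios are `NA` when the
#' denominator is zero.
#'
#' @param x a [GenotypeCohort].
#' @param effects data.frame from [classifyEffects()].
#' @param polarized data.frame from [polarizeSites()] (same cohort).
#' @param group species/population label (default as in
#'   [polarizeSites()]).
#' @param denominator `"hom_derived"` (default) or `"all_synonymous"`.
#' @return data.frame with one row per individual and a `lofGenes`
#'   attribute (named list of gene-id vectors).
#' @export
individualLoad <- function(x, effects, polarized, group = NULL,
                           denominator = c("hom_derived",
                                           "all_synonymous")) {
  stopifnot(is(x, "GenotypeCohort"))
  denominator <- match.arg(denominator)
  og <- isOutgroup(x)
  grp <- sampleGroups(x)
  if (is.null(group)) {
    gg <- unique(grp[!og])
    if (length(gg) != 1)
      stop("multiple groups present; specify 'group'")
    group <- gg
  }
  members <- colnames(x)[!og & grp == group]
  pol <- polarized[polarized$status == "polarized", , drop = FALSE]
  eff <- effects[effects$class %in% c("LOF", "missense", "synonymous"), ,
                 drop = FALSE]
  m <- merge(eff, pol[, c("site", "derivedDosage")], by = "site")
  gt <- genotypes(x)
  res <- data.frame(sample = members,
                    n_hom_derived_lof = 0L, n_genes_hom_lof = 0L,
                    n_hom_derived_missense = 0L,
                    n_hom_derived_synonymous = 0L,
                    stringsAsFactors = FALSE)
  lofGenes <- setNames(rep(list(character(0)), length(members)), members)
  if (nrow(m)) {
    for (k in seq_along(members)) {
      g <- gt[m$site, members[k]]
      homDer <- !is.na(g) & g == m$derivedDosage
      res$n_hom_derived_lof[k] <- sum(homDer & m$class == "LOF")
      res$n_hom_derived_missense[k] <- sum(homDer & m$class == "missense")
      res$n_hom_derived_synonymous[k] <-
        sum(homDer & m$class == "synonymous")
      lofGenes[[k]] <- unique(m$gene_id[homDer & m$class == "LOF"])
      res$n_genes_hom_lof[k] <- length(lofGenes[[k]])
    }
  }
  den <- if (denominator == "hom_derived") res$n_hom_derived_synonymous
         else rep(sum(m$class == "synonymous"), nrow(res))
  res$ratio_lof_syn <- ifelse(den > 0, res$n_hom_derived_lof / den, NA)
  res$ratio_mis_syn <- ifelse(den > 0, res$n_hom_derived_missense / den, NA)
  attr(res, "lofGenes") <- lofGenes
  res
}

#' Load summaries for every group in a cohort
#'
#' Runs [polarizeSites()] (per species group, independently) and
#' [individualLoad()] for each non-outgroup group.
#'
#' @inheritParams individualLoad
#' @param effects data.frame from [classifyEffects()]; computed from the
#'   cohort's ANN strings when omitted.
#' @return data.frame of per-individual load rows with a `group` column
#'   and a combined `lofGenes` attribute.
#' @export
cohortLoad <- function(x, effects = NULL,
                       denominator = c("hom_derived", "all_synonymous")) {
  denominator <- match.arg(denominator)
  effects <- effects %||% classifyEffects(x)
  og <- isOutgroup(x)
  grp <- sampleGroups(x)
  out <- list(); genes <- list()
  for (g in unique(grp[!og])) {
    pol <- polarizeSites(x, group = g, sites = effects$site)
    li <- individualLoad(x, effects, pol, group = g,
                         denominator = denominator)
    li$group <- g
    genes <- c(genes, attr(li, "lofGenes"))
    out[[length(out) + 1L]] <- li
  }
  res <- do.call(rbind, out)
  attr(res, "lofGenes") <- genes
  res
}

#' Candidate genes carrying homozygous-derived LOF mutations
#'
#' Per species/population, the set of genes with at least one
#' homozygous-derived LOF variant in at least one (retained) individual.
#'
#' @param loads result of [cohortLoad()] (its `lofGenes` attribute is
#'   used).
#' @param retained optional character vector restricting to retained
#'   individuals (e.g. from [pruneRelated()]).
#' @return Named list (per group) of character vectors of gene ids.
#' @export
candidateGeneScreen <- function(loads, retained = NULL) {
  genes <- attr(loads, "lofGenes")
  if (is.null(genes)) stop("'loads' lacks the lofGenes attribute")
  keep <- loads$sample
  if (!is.null(retained)) keep <- intersect(keep, retained)
  out <- list()
  for (g in unique(loads$group)) {
    ids <- intersect(loads$sample[loads$group == g], keep)
    out[[g]] <- sort(unique(unlist(genes[ids])))
  }
  out
}
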