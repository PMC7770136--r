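## KING-robust pairwise kinship from identity-by-state counts, and greedy
## pruning of consanguineous individuals.

#' Count identity-by-state states for a pair of individuals
#'
#' Over jointly non-missing sites, counts: `nIbs0` (one individual
#' homozygous reference, the other homozygous alternate), `nHetHet` (both
#' heterozygous), `nHetI`/`nHetJ` (heterozygous sites per individual) and
#' `nShared` (jointly non-missing sites).
#'
#' @param gi,gj integer dosage vectors (0/1/2, `NA` missing) of equal
#'   length.
#' @return A named list of class `IbsCounts`.
#' @examples
#' countIbsStates(c(0, 1, 2, 1, NA, 0), c(1, 1, 0, 0, 1, 0))
#' @export
countIbsStates <- function(gi, gj) {
  stopifnot(length(gi) == length(gj))
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok))
    stop("no jointly non-missing sites for this pair")
  gi <- gi[ok]; gj <- gj[ok]
  counts <- list(
    nIbs0 = sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L)),
    nHetHet = sum(gi == 1L & gj == 1L),
    nHetI = sum(gi == 1L),
    nHetJ = sum(gj == 1L),
    nShared = length(gi))
  class(counts) <- "IbsCounts"
  counts
}

#' KING-robust kinship coefficient from IBS-state counts
#'
#' The between-family robust estimator
#' `phi = (nHetHet - 2 * nIbs0) / (nHetI + nHetJ)`: 0.5 for duplicate
#' samples, about 0.25 for parent-offspring and full-sib pairs, and 0 in
#' expectation for unrelated individuals from one population. Negative
#' values indicate unrelated (or cross-population) pairs.
#'
#' @param counts an `IbsCounts` from [countIbsStates()].
#' @return A list with `phi` (NA with a warning when `nHetI + nHetJ` is
#'   zero) and the input `counts`.
#' @examples
#' kinshipCoefficient(list(nIbs0 = 10, nHetHet = 100,
#'   nHetI = 120, nHetJ = 140))$phi  # (100 - 20) / 260
#' @export
kinshipCoefficient <- function(counts) {
  denom <- counts$nHetI + counts$nHetJ
  if (is.na(denom) || denom <= 0) {
    warning("kinship undefined: no heterozygous sites in either individual")
    return(list(phi = NA_real_, counts = counts))
  }
  list(phi = (counts$nHetHet - 2 * counts$nIbs0) / denom, counts = counts)
}

#' All pairwise kinship estimates within groups
#'
#' Computes [kinshipCoefficient()] for every pair of non-outgroup
#' individuals, within each species/population group (cross-group pairs
#' are not estimated, matching per-species pruning).
#'
#' @param x a [GenotypeCohort] (typically after [applySiteFilters()]).
#' @param groups optional group labels overriding `sampleGroups(x)`.
#' @return A data.frame with one row per pair: `group`, `id1`, `id2`, the
#'   IBS counts and `phi`.
#' @export
pairwiseKinship <- function(x, groups = NULL) {
  stopifnot(is(x, "GenotypeCohort"))
  gt <- genotypes(x)
  grp <- groups %||% sampleGroups(x)
  keep <- !isOutgroup(x)
  out <- list()
  for (g in unique(grp[keep])) {
    ids <- colnames(x)[keep & grp == g]
    if (length(ids) < 2) next
    prs <- combn(ids, 2)
    for (k in seq_len(ncol(prs))) {
      cnt <- countIbsStates(gt[, prs[1, k]], gt[, prs[2, k]])
      phi <- suppressWarnings(kinshipCoefficient(cnt)$phi)
      out[[length(out) + 1L]] <- data.frame(
        group = g, id1 = prs[1, k], id2 = prs[2, k],
        nShared = cnt$nShared, nIbs0 = cnt$nIbs0, nHetHet = cnt$nHetHet,
        nHetI = cnt$nHetI, nHetJ = cnt$nHetJ, phi = phi,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(0), id1 = character(0),
                      id2 = character(0), nShared = integer(0),
                      nIbs0 = integer(0), nHetHet = integer(0),
                      nHetI = integer(0), nHetJ = integer(0),
                      phi = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Prune related individuals by greedy maximum degree
#'
#' Retains, per group, a set of individuals in which every pair has
#' kinship below the threshold (default 0: only pairs with negative
#' kinship coefficients are kept, the standard non-consanguineous
#' retention rule). While any pair is at or above the threshold, the
#' individual participating in the most such pairs is removed; ties are
#' broken toward the individual with lower sequencing depth (when
#' provided), then the lexicographically smallest id. Pairs with undefined
#' kinship are excluded from the graph with a warning.
#'
#' @param estimates data.frame from [pairwiseKinship()].
#' @param threshold kinship threshold; pairs with `phi >= threshold` are
#'   edges.
#' @param depth optional named numeric of per-sample sequencing depth used
#'   for tie-breaking.
#' @return Character vector of retained sample ids (all groups combined).
#' @export
pruneRelated <- function(estimates, threshold = 0, depth = NULL) {
  if (!nrow(estimates)) return(character(0))
  if (anyNA(estimates$phi)) {
    warning(sum(is.na(estimates$phi)),
            " pair(s) with undefined kinship excluded from pruning")
    estimates <- estimates[!is.na(estimates$phi), , drop = FALSE]
  }
  retained <- character(0)
  for (g in unique(estimates$group)) {
    eg <- estimates[estimates$group == g, , drop = FALSE]
    ids <- sort(unique(c(eg$id1, eg$id2)))
    edges <- eg[eg$phi >= threshold, c("id1", "id2"), drop = FALSE]
    while (nrow(edges) > 0) {
      deg <- table(factor(c(edges$id1, edges$id2), levels = ids))
      worst <- names(deg)[deg == max(deg)]
      if (length(worst) > 1 && !is.null(depth)) {
        d <- depth[worst]
        if (!anyNA(d)) worst <- worst[d == min(d)]
      }
      drop1 <- sort(worst)[1]
      ids <- setdiff(ids, drop1)
      edges <- edges[edges$id1 != drop1 & edges$id2 != drop1, , drop = FALSE]
    }
    retained <- c(retained, ids)
  }
  retained
}
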