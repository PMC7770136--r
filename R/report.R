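## Group summaries with rank-based comparisons.

#' Summarize per-individual metrics by group with rank-sum comparisons
#'
#' Computes mean, sd and n per metric per group, and a two-sided
#' Mann-Whitney rank-sum p-value for every group pair and metric (exact
#' when both groups have at most `exactMax` observations and no ties,
#' normal approximation with continuity correction otherwise). No
#' multiple-testing correction is applied by default; `adjust = "BH"`
#' adds Benjamini-Hochberg adjusted p-values across the comparisons of
#' each metric.
#'
#' @param data data.frame with a `group` column and numeric metric
#'   columns.
#' @param metrics character vector of metric column names (default: all
#'   numeric columns except `group`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param exactMax largest group size for which the exact test is used.
#' @return A list with `summary` (group, metric, n, mean, sd; sd is `NA`
#'   for singleton groups) and `comparisons` (metric, group1, group2, p,
#'   and `p_adj` when requested; comparisons involving singleton groups
#'   are flagged in `note`).
#' @examples
#' d <- data.frame(group = rep(c("a", "b"), each = 3),
#'                 he = c(1, 2, 3, 10, 11, 12))
#' summarizeGroups(d)$comparisons  # exact two-sided p = 0.1
#' @export
summarizeGroups <- function(data, metrics = NULL, adjust = c("none", "BH"),
                            exactMax = 25L) {
  adjust <- match.arg(adjust)
  stopifnot("group" %in% colnames(data))
  if (is.null(metrics))
    metrics <- setdiff(colnames(data)[vapply(data, is.numeric, logical(1))],
                       "group")
  stopifnot(length(metrics) >= 1, all(metrics %in% colnames(data)))
  groups <- unique(as.character(data$group))
  summ <- do.call(rbind, lapply(metrics, function(mname) {
    do.call(rbind, lapply(groups, function(g) {
      v <- data[[mname]][data$group == g]
      v <- v[!is.na(v)]
      data.frame(group = g, metric = mname, n = length(v),
                 mean = mean(v), sd = if (length(v) >= 2) sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  comp <- NULL
  if (length(groups) >= 2) {
    prs <- combn(groups, 2)
    comp <- do.call(rbind, lapply(metrics, function(mname) {
      do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
        v1 <- data[[mname]][data$group == prs[1, k]]
        v2 <- data[[mname]][data$group == prs[2, k]]
        v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
        useExact <- max(length(v1), length(v2)) <= exactMax
        p <- suppressWarnings(
          wilcox.test(v1, v2, alternative = "two.sided",
                      exact = useExact, correct = TRUE)$p.value)
        data.frame(metric = mname, group1 = prs[1, k], group2 = prs[2, k],
                   p = p,
                   note = if (length(v1) < 2 || length(v2) < 2)
                     "singleton group" else "",
                   stringsAsFactors = FALSE)
      }))
    }))
    if (adjust == "BH")
      comp$p_adj <- ave(comp$p, comp$metric,
                        FUN = function(p) p.adjust(p, "BH"))
  }
  list(summary = summ, comparisons = comp)
}
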