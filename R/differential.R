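# Per-feature univariate statistics: classical one-way ANOVA across all
# cell types and pairwise fold change / percent difference on normalized
# intensities, matching the convention of reporting raw (uncorrected)
# ANOVA p-values at alpha = 0.05, with an optional BH-FDR flag.

#' Classical one-way ANOVA
#'
#' F = (SSB/dfB) / (SSW/dfW) with the p-value from the upper tail of the
#' F distribution.
#'
#' @param groups List of numeric vectors, one per group; >= 2 groups
#'   with >= 2 values each, not all values identical.
#' @return List with `F_statistic`, `p_value`, `df_between`, `df_within`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) stop("values must be finite")
  if (max(values) == min(values))
    stop("degenerate input: all values identical")
  grand <- mean(values)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(seq_along(groups), function(i)
    sum((groups[[i]] - means[i])^2), numeric(1)))
  if (ssw == 0) stop("degenerate input: zero within-group variance")
  df_b <- length(groups) - 1
  df_w <- sum(sizes) - length(groups)
  f <- (ssb / df_b) / (ssw / df_w)
  list(F_statistic = f,
       p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w)
}

#' Pairwise fold change and percent difference for one feature
#'
#' Fold change is `mean(group_a) / mean(group_b)` of (normalized)
#' intensities; percent difference is `(fold - 1) * 100`. The p-value is
#' the omnibus one-way ANOVA across all groups of the table, and the
#' direction is `up` iff fold > 1 and p < alpha, `down` iff fold < 1 and
#' p < alpha, else `unchanged`. No multiplicity correction is applied
#' here (see [differential_table()] for the BH option).
#'
#' @param table A `feature_table` (normalize first).
#' @param feature Feature id.
#' @param group_a,group_b Group labels (numerator, denominator).
#' @param alpha Significance level (default 0.05).
#' @return One-row data frame: `feature_id`, `comparison`, `fold_change`,
#'   `percent_difference`, `p_value`, `direction`.
#' @export
pairwise_change <- function(table, feature, group_a, group_b, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (!feature %in% colnames(table$intensities))
    stop("unknown feature: ", feature)
  v <- table$intensities[, feature]
  g <- as.character(table$group)
  for (gr in c(group_a, group_b))
    if (sum(g == gr & !is.na(v)) < 2)
      stop("group ", gr, " needs >= 2 non-missing replicates")
  groups <- split(v[!is.na(v)], g[!is.na(v)])
  mean_a <- mean(groups[[group_a]])
  mean_b <- mean(groups[[group_b]])
  if (mean_b <= 0) stop("denominator group mean must be > 0")
  if (mean_a < 0) stop("group means must be non-negative")
  fold <- mean_a / mean_b
  p <- one_way_anova(groups)$p_value
  direction <- if (p < alpha && fold > 1) "up"
  else if (p < alpha && fold < 1) "down"
  else "unchanged"
  data.frame(feature_id = feature,
             comparison = paste0(group_a, "/", group_b),
             fold_change = fold,
             percent_difference = (fold - 1) * 100,
             p_value = p,
             direction = direction,
             stringsAsFactors = FALSE)
}

#' Differential table over all features
#'
#' Runs [pairwise_change()] for every feature. Features for which the
#' ANOVA is degenerate (e.g. zero within-group variance) are reported
#' with `NA` statistics rather than dropped.
#'
#' @param table A `feature_table` (normalize first).
#' @param group_a,group_b Comparison groups (numerator, denominator).
#' @param alpha Significance level for the direction call.
#' @param adjust `"none"` (default, raw ANOVA p-values) or `"BH"` for
#'   Benjamini-Hochberg FDR before the direction call.
#' @return Data frame, one row per feature.
#' @export
differential_table <- function(table, group_a, group_b, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  feats <- colnames(table$intensities)
  rows <- lapply(feats, function(f) {
    tryCatch(pairwise_change(table, f, group_a, group_b, alpha = alpha),
             error = function(e)
               data.frame(feature_id = f,
                          comparison = paste0(group_a, "/", group_b),
                          fold_change = NA_real_,
                          percent_difference = NA_real_,
                          p_value = NA_real_,
                          direction = "not measured",
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
    ok <- !is.na(out$p_value)
    out$direction[ok] <- ifelse(out$p_value[ok] < alpha & out$fold_change[ok] > 1,
                                "up",
                         ifelse(out$p_value[ok] < alpha & out$fold_change[ok] < 1,
                                "down", "unchanged"))
  }
  rownames(out) <- NULL
  out
}

#' Write a differential table to TSV
#'
#' The output is consumed directly by [attach_attributes()] as a
#' node-attribute source.
#'
#' @param results Data frame from [differential_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
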