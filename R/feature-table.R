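# Samples x features intensity tables with group labels and a platform
# tag; total-intensity normalization, cross-platform merging, and
# cross-platform concordance checks.

#' Construct a feature table
#'
#' @param intensities Numeric matrix, samples in rows, features in
#'   columns; non-negative, `NA` encodes a missing measurement (never 0).
#' @param group Factor or character vector of per-sample group labels
#'   (e.g. m15 / mESC / iPSC).
#' @param platform Platform tag, e.g. `"nanoESI"`, `"GC-TOF"`,
#'   `"HILIC-QTOF"`, `"RP-QTOF"`.
#' @param sample_ids,feature_ids Optional identifier vectors; taken from
#'   dimnames when omitted.
#' @return A `feature_table` object.
#' @export
feature_table <- function(intensities, group, platform = "nanoESI",
                          sample_ids = rownames(intensities),
                          feature_ids = colnames(intensities)) {
  intensities <- as.matrix(intensities)
  if (is.null(sample_ids))
    sample_ids <- paste0("sample_", seq_len(nrow(intensities)))
  if (is.null(feature_ids))
    feature_ids <- paste0("feature_", seq_len(ncol(intensities)))
  if (length(sample_ids) != nrow(intensities) ||
      length(feature_ids) != ncol(intensities))
    stop("id lengths do not match matrix dimensions")
  if (length(group) != nrow(intensities))
    stop("group must have one label per sample")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  dimnames(intensities) <- list(sample_ids, feature_ids)
  structure(list(intensities = intensities,
                 group = factor(group),
                 platform = platform),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table [", x$platform, "]: ", nrow(x$intensities),
      " samples x ", ncol(x$intensities), " features\n", sep = "")
  print(table(x$group))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Total-intensity normalization
#'
#' Divides each sample's intensities by the sample total so every row
#' sums to one; samples are then compared on relative composition.
#' Missing values are ignored in the total. Idempotent and invariant to
#' per-sample rescaling.
#'
#' @param table A `feature_table`.
#' @return Normalized `feature_table`.
#' @export
normalize_total_intensity <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- rowSums(table$intensities, na.rm = TRUE)
  bad <- totals <= 0
  if (any(bad))
    stop("sample(s) with zero total intensity: ",
         paste(rownames(table$intensities)[bad], collapse = ", "))
  table$intensities <- table$intensities / totals
  table
}

#' Merge per-platform feature tables
#'
#' Column-wise concatenation over the intersection of samples. Feature
#' ids are made unique by platform qualification (`feature|platform`);
#' features detected on several platforms are retained separately so
#' they can be compared rather than silently averaged. Values are copied
#' bit-for-bit (no rescaling), so normalize per platform first.
#'
#' @param tables List of `feature_table` objects.
#' @return Merged `feature_table` (platform tag `"merged"`).
#' @export
merge_platforms <- function(tables) {
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1) return(tables[[1]])
  shared <- Reduce(intersect, lapply(tables, function(t) rownames(t$intensities)))
  if (length(shared) == 0) stop("no samples shared across platforms")
  g0 <- tables[[1]]$group[match(shared, rownames(tables[[1]]$intensities))]
  mats <- lapply(tables, function(t) {
    idx <- match(shared, rownames(t$intensities))
    g <- t$group[idx]
    if (!all(as.character(g) == as.character(g0)))
      stop("group labels disagree across platforms for shared samples")
    m <- t$intensities[idx, , drop = FALSE]
    colnames(m) <- paste0(colnames(m), "|", t$platform)
    m
  })
  feature_table(do.call(cbind, mats), group = g0, platform = "merged",
                sample_ids = shared)
}

#' Cross-platform quantitative concordance
#'
#' Pearson correlation of per-sample intensities for features measured
#' on two platforms, over their shared samples. Zero-variance features
#' yield an undefined (NA) correlation, flagged rather than fabricated.
#'
#' @param table_a,table_b `feature_table` objects sharing >= 3 samples.
#' @param shared_feature_map Data frame with columns `feature_a`,
#'   `feature_b` naming the mapped feature pair on each platform.
#' @return Data frame `feature_a`, `feature_b`, `r`, `n_samples`,
#'   `defined`.
#' @export
cross_platform_concordance <- function(table_a, table_b, shared_feature_map) {
  shared <- intersect(rownames(table_a$intensities),
                      rownames(table_b$intensities))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  out <- shared_feature_map
  out$r <- NA_real_; out$n_samples <- NA_integer_; out$defined <- FALSE
  for (i in seq_len(nrow(out))) {
    a <- table_a$intensities[shared, out$feature_a[i]]
    b <- table_b$intensities[shared, out$feature_b[i]]
    ok <- stats::complete.cases(a, b)
    out$n_samples[i] <- sum(ok)
    if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
      out$r[i] <- stats::cor(a[ok], b[ok])
      out$defined[i] <- TRUE
    }
  }
  out
}

#' Write a feature table to CSV/TSV
#'
#' Layout: columns `sample_id`, `group`, `platform`, then one column per
#' feature.
#'
#' @param table A `feature_table`.
#' @param path Output path; extension `.csv` selects comma separation,
#'   anything else tab.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table$intensities),
                   group = as.character(table$group),
                   platform = table$platform,
                   table$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "platform")
  if (!all(required %in% names(df)))
    stop("feature table file must have columns: ",
         paste(required, collapse = ", "))
  feats <- setdiff(names(df), required)
  m <- as.matrix(df[, feats, drop = FALSE])
  feature_table(m, group = df$group, platform = df$platform[1],
                sample_ids = df$sample_id, feature_ids = feats)
}
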