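# Multivariate fingerprint statistics: unsupervised PCA and supervised
# PLS-DA (NIPALS with X deflation), both returning a common classed
# result with scores, loadings and percent variance explained.

as_intensity_matrix <- function(x) {
  if (inherits(x, "feature_table")) return(x$intensities)
  as.matrix(x)
}

new_ordination <- function(scores, loadings, explained, method, n_components,
                           center, group = NULL, weights = NULL) {
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_pct = explained, method = method,
                 n_components = n_components, center = center,
                 group = group, weights = weights),
            class = "ordination")
}

#' Principal component analysis of a feature table
#'
#' Mean-centered PCA (optionally unit-variance scaled) with components
#' ordered by decreasing variance and a deterministic sign convention:
#' within each component the loading of largest magnitude is positive.
#' `explained_variance_pct` is each retained component's share of the
#' total variance, so over all components the shares sum to 100.
#'
#' @param table A `feature_table` or numeric samples x features matrix.
#' @param n_components Number of components to retain (at most
#'   `min(samples - 1, features)`).
#' @param scale Logical; unit-variance scale features (default `FALSE`:
#'   intensities are already normalized to relative composition).
#' @return An `ordination` object.
#' @export
pca <- function(table, n_components = 2, scale = FALSE) {
  x <- as_intensity_matrix(table)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 samples and >= 2 features")
  max_comp <- min(nrow(x) - 1, ncol(x))
  if (n_components > max_comp)
    stop("n_components exceeds min(samples - 1, features) = ", max_comp)
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  total_var <- sum(fit$sdev^2)
  keep <- seq_len(n_components)
  scores <- fit$x[, keep, drop = FALSE]
  loadings <- fit$rotation[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in keep) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  new_ordination(scores, loadings,
                 100 * fit$sdev[keep]^2 / total_var,
                 "PCA", n_components, fit$center,
                 group = if (inherits(table, "feature_table")) table$group)
}

#' PLS-DA of a grouped feature table
#'
#' Partial least squares discriminant analysis: the group factor is
#' expanded to a centered indicator matrix and sequential NIPALS
#' components are extracted with deflation of X (convergence tolerance
#' 1e-10, at most 500 iterations per component). Deterministic under a
#' fixed input order, with the PCA sign convention applied to the
#' X weights. `explained_variance_pct` is the share of the (centered)
#' X variance captured by each component.
#'
#' @param table A `feature_table`, or a matrix together with `group`.
#' @param n_components Number of latent components.
#' @param group Group labels when `table` is a bare matrix.
#' @param tol,max_iter NIPALS convergence controls.
#' @return An `ordination` object (with X weights in `$weights`).
#' @export
pls_da <- function(table, n_components = 2, group = NULL,
                   tol = 1e-10, max_iter = 500) {
  x <- as_intensity_matrix(table)
  if (inherits(table, "feature_table")) group <- table$group
  if (is.null(group)) stop("group labels are required")
  group <- factor(group)
  if (nlevels(group) < 2) stop("PLS-DA requires >= 2 groups")
  if (length(group) != nrow(x)) stop("one group label per sample required")
  n_components <- min(n_components, nrow(x) - 1, ncol(x))

  center <- colMeans(x)
  X <- sweep(x, 2, center)
  Y <- stats::model.matrix(~ 0 + group)
  Y <- sweep(Y, 2, colMeans(Y))
  total_var <- sum(X^2)

  n <- nrow(X); p <- ncol(X)
  Tm <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components)
  W <- matrix(0, p, n_components)
  explained <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Y[, which.max(apply(Y, 2, stats::var)), drop = TRUE]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u))
      wn <- sqrt(sum(w^2))
      if (wn == 0) break
      w <- w / wn
      t_new <- drop(X %*% w)
      q <- drop(crossprod(Y, t_new)) / sum(t_new^2)
      qn <- sqrt(sum(q^2))
      if (qn > 0) u <- drop(Y %*% q) / sum(q^2)
      if (sqrt(sum((t_new - t_old)^2)) < tol) { t_old <- t_new; break }
      t_old <- t_new
    }
    t_a <- t_old
    if (all(t_a == 0) || !all(is.finite(t_a))) break
    p_a <- drop(crossprod(X, t_a)) / sum(t_a^2)
    # sign convention on weights
    i <- which.max(abs(w))
    if (w[i] < 0) { w <- -w; t_a <- -t_a; p_a <- -p_a }
    Tm[, a] <- t_a; P[, a] <- p_a; W[, a] <- w
    explained[a] <- 100 * sum(t_a^2) * sum(p_a^2) / total_var
    X <- X - tcrossprod(t_a, p_a)
    c_a <- drop(crossprod(Y, t_a)) / sum(t_a^2)
    Y <- Y - tcrossprod(t_a, c_a)
  }
  dimnames(Tm) <- list(rownames(x), paste0("comp", seq_len(n_components)))
  dimnames(P) <- list(colnames(x), colnames(Tm))
  dimnames(W) <- dimnames(P)
  new_ordination(Tm, P, explained, "PLS-DA", n_components, center,
                 group = group, weights = W)
}

#' @export
print.ordination <- function(x, ...) {
  cat(x$method, "with", x$n_components, "components\n")
  cat("  variance explained (%):",
      paste(sprintf("%.1f", x$explained_variance_pct), collapse = ", "), "\n")
  cat("  samples:", nrow(x$scores), "\n")
  invisible(x)
}

#' Scatter plot of two ordination components
#'
#' @param x An `ordination`.
#' @param components Length-2 integer vector of components to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ordination <- function(x, components = c(1, 2), ...) {
  s <- x$scores[, components, drop = FALSE]
  grp <- if (is.null(x$group)) factor(rep("all", nrow(s))) else x$group
  lab <- paste0(x$method, " comp ", components,
                sprintf(" (%.1f%%)", x$explained_variance_pct[components]))
  graphics::plot(s[, 1], s[, 2], col = as.integer(grp), pch = 19,
                 xlab = lab[1], ylab = lab[2], ...)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_len(nlevels(grp)), pch = 19, bty = "n")
  invisible(x)
}

#' Silhouette-based group separation on ordination scores
#'
#' Mean silhouette width of the samples of the contrasted groups, using
#' Euclidean distance on the selected score components. Values near 1
#' mean well-separated clusters; values near 0 mean overlapping clouds.
#'
#' @param ordination An `ordination` with group labels.
#' @param groups Optional character vector: restrict to these groups
#'   (e.g. `c("mESC", "iPSC")`). Groups may also be merged by passing a
#'   named list, e.g. `list(pluripotent = c("mESC", "iPSC"), m15 = "m15")`.
#' @param components Score components to use (default 1:2).
#' @return Mean silhouette width (numeric scalar).
#' @export
separation_silhouette <- function(ordination, groups = NULL,
                                  components = c(1, 2)) {
  stopifnot(inherits(ordination, "ordination"), !is.null(ordination$group))
  components <- components[components <= ncol(ordination$scores)]
  s <- ordination$scores[, components, drop = FALSE]
  g <- as.character(ordination$group)
  if (is.list(groups)) {
    merged <- rep(NA_character_, length(g))
    for (nm in names(groups)) merged[g %in% groups[[nm]]] <- nm
    keep <- !is.na(merged); g <- merged[keep]; s <- s[keep, , drop = FALSE]
  } else if (!is.null(groups)) {
    keep <- g %in% groups; g <- g[keep]; s <- s[keep, , drop = FALSE]
  }
  if (length(unique(g)) < 2) stop("need >= 2 groups for a silhouette")
  sil <- cluster::silhouette(as.integer(factor(g)), stats::dist(s))
  mean(sil[, "sil_width"])
}

#' Write ordination scores and loadings to TSV files
#'
#' @param ordination An `ordination`.
#' @param scores_path,loadings_path Output paths (`NULL` skips a file).
#' @return Invisibly, the paths written.
#' @export
write_ordination <- function(ordination, scores_path, loadings_path = NULL) {
  sc <- data.frame(sample_id = rownames(ordination$scores),
                   group = if (is.null(ordination$group)) NA else
                     as.character(ordination$group),
                   ordination$scores, check.names = FALSE)
  utils::write.table(sc, scores_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(loadings_path)) {
    ld <- data.frame(feature_id = rownames(ordination$loadings),
                     ordination$loadings, check.names = FALSE)
    utils::write.table(ld, loadings_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(scores_path, loadings_path))
}
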