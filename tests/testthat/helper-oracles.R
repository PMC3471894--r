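# Independent oracles used across the test files. Constants and
# formulas here are entered separately from the package internals so
# agreement is a genuine cross-check.

# Higher-precision monoisotopic atomic masses (CODATA/IUPAC), entered
# independently of the package's 6-decimal table.
oracle_atomic_mass <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928
)

# Brute-force atom-sum mass.
oracle_mass <- function(formula) {
  counts <- unlist(formula)
  if (length(counts) == 0) return(0)
  sum(counts * oracle_atomic_mass[names(counts)])
}

# Classical one-way ANOVA F via R's own fitter, as an oracle.
oracle_anova_f <- function(groups) {
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  unname(stats::oneway.test(values ~ g, var.equal = TRUE)$statistic)
}

# Random fingerprint with a given number of set bits.
random_fp <- function(nbits = 1024, on = 120) {
  fingerprint(sample.int(nbits, on), nbits = nbits)
}

# Brute-force all-pairs network edge set: Tanimoto strictly above the
# threshold, plus reaction pairs, as a sorted data frame.
oracle_edge_set <- function(fps, ids, rpair_table, threshold) {
  rows <- list()
  n <- length(fps)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    num <- length(intersect(unclass(fps[[i]]), unclass(fps[[j]])))
    den <- length(union(unclass(fps[[i]]), unclass(fps[[j]])))
    sc <- round(1000 * num / den)
    if (sc > threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        from = min(ids[i], ids[j]), to = max(ids[i], ids[j]),
        type = "tanimoto", stringsAsFactors = FALSE)
  }
  if (!is.null(rpair_table)) for (r in seq_len(nrow(rpair_table))) {
    a <- rpair_table$id_a[r]; b <- rpair_table$id_b[r]
    if (a %in% ids && b %in% ids && a != b)
      rows[[length(rows) + 1L]] <- data.frame(
        from = min(a, b), to = max(a, b), type = "rpair",
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out[order(out$from, out$to, out$type), , drop = FALSE]
}

# Small deterministic feature table used by several files.
toy_table <- function() {
  set.seed(99)
  m <- matrix(rexp(6 * 4, rate = 0.01), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
  feature_table(m, group = rep(c("a", "b"), each = 3), platform = "nanoESI")
}
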