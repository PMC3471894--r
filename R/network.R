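# Metabolite network mapping: chemical-similarity edges from fingerprint
# Tanimoto scores (strict > threshold on the 0-1000 scale), biochemical
# edges from a reaction-pair table, node attributes from differential
# statistics, and Cytoscape-readable exports (GraphML, SIF + node TSV).

#' Assemble metabolite nodes
#'
#' @param id Character vector of unique metabolite ids.
#' @param name Display names (defaults to `id`).
#' @param fingerprints List of `fingerprint` objects (one per node), a
#'   character vector of 0/1 bit strings, or `NULL` to compute from
#'   `smiles`.
#' @param smiles Optional SMILES (used when `fingerprints` is `NULL`).
#' @param kegg_id Optional KEGG compound ids.
#' @return A `metabolite_nodes` data frame with a `fingerprint`
#'   list-column.
#' @export
metabolite_nodes <- function(id, name = id, fingerprints = NULL,
                             smiles = NA_character_,
                             kegg_id = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("metabolite ids must be unique")
  if (is.null(fingerprints)) {
    if (all(is.na(smiles))) stop("supply fingerprints or smiles")
    fingerprints <- fingerprint_from_smiles(stats::setNames(smiles, id))
  }
  if (is.character(fingerprints))
    fingerprints <- lapply(fingerprints, parse_fingerprint)
  if (length(fingerprints) != length(id))
    stop("need one fingerprint per node")
  nb <- unique(vapply(fingerprints, attr, integer(1), "nbits"))
  if (length(nb) != 1) stop("all fingerprints must have the same length")
  out <- data.frame(id = id, name = as.character(name),
                    smiles = smiles, kegg_id = kegg_id,
                    stringsAsFactors = FALSE)
  out$fingerprint <- unname(fingerprints)
  class(out) <- c("metabolite_nodes", "data.frame")
  out
}

#' Read node metadata from TSV
#'
#' Expected columns: `id`, `name`, optional `smiles`, `kegg_id`, and
#' either a `fingerprint` column of 0/1 bit strings or parseable SMILES.
#'
#' @param path TSV path.
#' @return A `metabolite_nodes` data frame.
#' @export
read_metabolite_nodes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "",
                          colClasses = "character")
  metabolite_nodes(
    id = df$id,
    name = if ("name" %in% names(df)) df$name else df$id,
    fingerprints = if ("fingerprint" %in% names(df)) df$fingerprint,
    smiles = if ("smiles" %in% names(df)) df$smiles else NA_character_,
    kegg_id = if ("kegg_id" %in% names(df)) df$kegg_id else NA_character_)
}

#' Build the metabolite network
#'
#' Edge set: all node pairs with Tanimoto similarity strictly above
#' `threshold` (type `tanimoto`, carrying the 0-1000 score) plus all
#' pairs listed in the reaction-pair table (type `rpair`, independent of
#' similarity). A pair may carry both edge types; isolated nodes are
#' retained. Reaction-pair rows referencing unknown ids are ignored with
#' a warning.
#'
#' @param nodes A `metabolite_nodes` data frame.
#' @param rpair_table Data frame with columns `id_a`, `id_b` (and
#'   optionally `rpair_id`), or `NULL` for none.
#' @param threshold Tanimoto threshold on the 0-1000 scale (strict >).
#' @return A `metabolite_network` (fields `graph`, `nodes`, `threshold`).
#' @export
build_network <- function(nodes, rpair_table = NULL, threshold = 700) {
  stopifnot(inherits(nodes, "metabolite_nodes"))
  n <- nrow(nodes)
  edges <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        sc <- tanimoto(nodes$fingerprint[[i]], nodes$fingerprint[[j]])
        if (sc > threshold)
          edges[[length(edges) + 1L]] <-
            data.frame(from = nodes$id[i], to = nodes$id[j],
                       type = "tanimoto", tanimoto_score = sc,
                       rpair_id = "", stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(rpair_table) && nrow(rpair_table) > 0) {
    known <- rpair_table$id_a %in% nodes$id & rpair_table$id_b %in% nodes$id
    if (any(!known))
      warning(sum(!known), " reaction-pair row(s) reference unknown ",
              "metabolite ids and were ignored")
    rp <- rpair_table[known, , drop = FALSE]
    if (nrow(rp) > 0) {
      # unordered pair, at most one rpair edge per pair
      key <- ifelse(rp$id_a < rp$id_b, paste(rp$id_a, rp$id_b),
                    paste(rp$id_b, rp$id_a))
      rp <- rp[!duplicated(key), , drop = FALSE]
      rp <- rp[rp$id_a != rp$id_b, , drop = FALSE]
      if (nrow(rp) > 0)
        edges[[length(edges) + 1L]] <-
          data.frame(from = rp$id_a, to = rp$id_b, type = "rpair",
                     tanimoto_score = NA_integer_,
                     rpair_id = if ("rpair_id" %in% names(rp))
                       rp$rpair_id else "",
                     stringsAsFactors = FALSE)
    }
  }
  edge_df <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), type = character(0),
               tanimoto_score = integer(0), rpair_id = character(0),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                     vertices = nodes[, "id", drop = FALSE])
  igraph::V(g)$name_label <- nodes$name
  structure(list(graph = g, nodes = nodes, threshold = threshold),
            class = "metabolite_network")
}

#' @export
print.metabolite_network <- function(x, ...) {
  et <- igraph::E(x$graph)$type
  cat("Metabolite network:", igraph::vcount(x$graph), "nodes,",
      sum(et == "tanimoto"), "tanimoto edge(s) (threshold >",
      x$threshold, "),", sum(et == "rpair"), "rpair edge(s)\n")
  invisible(x)
}

#' Edge list of a metabolite network
#'
#' @param network A `metabolite_network`.
#' @return Data frame `from`, `to`, `type`, `tanimoto_score` with
#'   unordered pairs ordered lexicographically.
#' @export
network_edges <- function(network) {
  g <- network$graph
  if (igraph::ecount(g) == 0)
    return(data.frame(from = character(0), to = character(0),
                      type = character(0), tanimoto_score = integer(0),
                      stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  out <- data.frame(from = pmin(el[, 1], el[, 2]),
                    to = pmax(el[, 1], el[, 2]),
                    type = igraph::E(g)$type,
                    tanimoto_score = igraph::E(g)$tanimoto_score,
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to, out$type), , drop = FALSE]
}

#' Attach differential statistics as node attributes
#'
#' Node color class: `up` (red) iff p < alpha and fold > 1; `down`
#' (blue) iff p < alpha and fold < 1; else `unchanged` (white). Nodes
#' without a matching differential result get `not measured` and the
#' minimum size. Node size is `s_min + k * |log2(fold_change)|`, clamped
#' to `[s_min, s_max]`, so size scales with fold change symmetrically
#' for increases and decreases. Re-attaching identical statistics is a
#' no-op.
#'
#' @param network A `metabolite_network`.
#' @param differential_results Data frame from [differential_table()]
#'   (matched to nodes via `feature_id`).
#' @param alpha Significance level (default 0.05).
#' @param s_min,s_max,k Node-size mapping parameters.
#' @return The network with `color_class`, `size`, `fold_change`,
#'   `p_value` vertex attributes.
#' @export
attach_attributes <- function(network, differential_results, alpha = 0.05,
                              s_min = 20, s_max = 80, k = 20) {
  g <- network$graph
  ids <- igraph::V(g)$name
  idx <- match(ids, differential_results$feature_id)
  fold <- differential_results$fold_change[idx]
  p <- differential_results$p_value[idx]
  color_class <- ifelse(is.na(idx) | is.na(fold) | is.na(p), "not measured",
                 ifelse(p < alpha & fold > 1, "up",
                 ifelse(p < alpha & fold < 1, "down", "unchanged")))
  size <- ifelse(is.na(fold) | fold <= 0, s_min,
                 pmin(s_max, pmax(s_min, s_min + k * abs(log2(fold)))))
  igraph::V(g)$color_class <- color_class
  igraph::V(g)$size <- size
  igraph::V(g)$fold_change <- ifelse(is.na(fold), NaN, fold)
  igraph::V(g)$p_value <- ifelse(is.na(p), NaN, p)
  network$graph <- g
  network
}

#' Export a metabolite network for Cytoscape
#'
#' `graphml` writes a single GraphML file with typed edges and node
#' attributes; `sif` writes a SIF edge file plus a node-attribute TSV.
#' `all` writes both.
#'
#' @param network A `metabolite_network`.
#' @param path Output path without extension (files get `.graphml`,
#'   `.sif`, `.nodes.tsv`).
#' @param format `"graphml"`, `"sif"` or `"all"`.
#' @return Character vector of files written, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif", "all")) {
  if (!format[1] %in% c("graphml", "sif", "all"))
    stop("unsupported format '", format[1],
         "'; supported formats: graphml, sif, all")
  format <- format[1]
  g <- network$graph
  # igraph cannot serialize NA integers to GraphML; use -1 sentinel
  if (igraph::ecount(g) > 0) {
    sc <- igraph::E(g)$tanimoto_score
    igraph::E(g)$tanimoto_score <- ifelse(is.na(sc), -1L, as.integer(sc))
  }
  files <- character(0)
  if (format %in% c("graphml", "all")) {
    f <- paste0(path, ".graphml")
    igraph::write_graph(g, f, format = "graphml")
    files <- c(files, f)
  }
  if (format %in% c("sif", "all")) {
    f_sif <- paste0(path, ".sif")
    ed <- network_edges(network)
    writeLines(if (nrow(ed) > 0)
      paste(ed$from, ed$type, ed$to) else character(0), f_sif)
    f_nodes <- paste0(path, ".nodes.tsv")
    va <- igraph::vertex_attr(g)
    nd <- data.frame(id = va$name,
                     name = if (!is.null(va$name_label)) va$name_label else va$name,
                     stringsAsFactors = FALSE)
    for (a in c("color_class", "size", "fold_change", "p_value"))
      if (!is.null(va[[a]])) nd[[a]] <- va[[a]]
    utils::write.table(nd, f_nodes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f_sif, f_nodes)
  }
  invisible(files)
}

#' Read a GraphML network written by [export_network()]
#'
#' @param path GraphML file path.
#' @return A `metabolite_network` (without fingerprints; `nodes` holds
#'   ids and any exported attributes).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::ecount(g) > 0) {
    sc <- igraph::E(g)$tanimoto_score
    if (!is.null(sc)) igraph::E(g)$tanimoto_score <-
      ifelse(sc < 0, NA_integer_, as.integer(sc))
  }
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(id = va$name,
                      name = if (!is.null(va$name_label)) va$name_label
                      else va$name,
                      stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = nodes, threshold = NA),
            class = "metabolite_network")
}

#' Read a reaction-pair table from TSV
#'
#' Expected columns `id_a`, `id_b`, optional `rpair_id` — the shape of a
#' KEGG RPAIR-style export.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_rpair_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("id_a", "id_b") %in% names(df)))
    stop("reaction-pair table needs columns id_a, id_b")
  df
}
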