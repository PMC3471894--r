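# Fingerprints, Tanimoto scores and metabolite-network construction.

test_that("tanimoto scores follow the set-overlap definition", {
  a <- fingerprint(c(1, 2, 3), nbits = 16)
  b <- fingerprint(c(2, 3, 4), nbits = 16)
  expect_identical(tanimoto(a, a), 1000L)
  expect_identical(tanimoto(a, b), 500L)  # 2 shared / 4 union
  expect_identical(tanimoto(a, fingerprint(c(10, 11), nbits = 16)), 0L)
  e <- fingerprint(integer(0), nbits = 16)
  expect_error(tanimoto(e, e), "undefined")
  expect_error(tanimoto(a, fingerprint(1, nbits = 8)), "lengths differ")
})

test_that("fingerprints round-trip through bit strings", {
  fp <- fingerprint(c(2, 5, 7), nbits = 8)
  s <- fingerprint_string(fp)
  expect_equal(s, "01001010")
  expect_equal(unclass(parse_fingerprint(s)), c(2L, 5L, 7L),
               ignore_attr = TRUE)
  expect_error(parse_fingerprint("01x1"), "0/1")
})

test_that("network edges equal the brute-force all-pairs rule", {
  set.seed(61)
  n <- 30
  ids <- sprintf("met%02d", seq_len(n))
  fps <- lapply(seq_len(n), function(i) random_fp(256, on = 60))
  # force some similar pairs
  fps[[2]] <- fingerprint(c(unclass(fps[[1]])[1:55], 200:204), nbits = 256)
  fps[[10]] <- fps[[9]]
  rp <- data.frame(id_a = c("met01", "met05", "met29", "ghost"),
                   id_b = c("met20", "met06", "met30", "met02"),
                   stringsAsFactors = FALSE)
  nodes <- metabolite_nodes(ids, fingerprints = fps)
  expect_warning(net <- build_network(nodes, rp, threshold = 700),
                 "unknown")
  got <- network_edges(net)[, c("from", "to", "type")]
  want <- oracle_edge_set(fps, ids, rp[rp$id_a != "ghost", ], 700)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # isolated nodes are retained
  expect_equal(igraph::vcount(net$graph), n)
})

test_that("rpair edges ignore similarity; identical structures link", {
  fp1 <- random_fp(128, 30)
  nodes <- metabolite_nodes(c("a", "b"), fingerprints = list(fp1, fp1))
  net <- build_network(nodes, NULL)
  ed <- network_edges(net)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$type, "tanimoto")
  expect_equal(ed$tanimoto_score, 1000L)

  set.seed(62)
  dissim <- metabolite_nodes(c("a", "b"),
                             fingerprints = list(random_fp(128, 30),
                                                 random_fp(128, 30)))
  net2 <- build_network(dissim, data.frame(id_a = "a", id_b = "b"))
  ed2 <- network_edges(net2)
  expect_equal(ed2$type, "rpair")
})

test_that("raising the Tanimoto threshold never adds edges", {
  set.seed(63)
  fps <- lapply(1:15, function(i) random_fp(128, 40))
  fps[[3]] <- fingerprint(c(unclass(fps[[2]])[1:36], 100:103), nbits = 128)
  nodes <- metabolite_nodes(sprintf("m%02d", 1:15), fingerprints = fps)
  prev <- NULL
  for (thr in c(500, 700, 900)) {
    ed <- network_edges(build_network(nodes, NULL, threshold = thr))
    key <- paste(ed$from, ed$to)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("differential attributes map to color and size", {
  set.seed(64)
  nodes <- metabolite_nodes(c("up", "down", "flat", "unmeasured"),
                            fingerprints = lapply(1:4, function(i)
                              random_fp(64, 16)))
  net <- build_network(nodes, NULL)
  d <- data.frame(feature_id = c("up", "down", "flat"),
                  fold_change = c(2.0, 0.5, 1.0),
                  p_value = c(0.01, 0.20, 0.80),
                  stringsAsFactors = FALSE)
  net <- attach_attributes(net, d, alpha = 0.05, s_min = 20, s_max = 80,
                           k = 20)
  v <- igraph::vertex_attr(net$graph)
  get <- function(a, id) v[[a]][v$name == id]
  expect_equal(get("color_class", "up"), "up")
  expect_equal(get("size", "up"), 40)               # s_min + k * |log2 2|
  expect_equal(get("color_class", "down"), "unchanged")  # p = 0.20
  expect_equal(get("size", "flat"), 20)             # |log2 1| = 0
  expect_equal(get("color_class", "unmeasured"), "not measured")
  expect_equal(get("size", "unmeasured"), 20)
  # idempotence: re-attaching identical statistics changes nothing
  net2 <- attach_attributes(net, d, alpha = 0.05, s_min = 20, s_max = 80,
                            k = 20)
  expect_equal(igraph::vertex_attr(net2$graph),
               igraph::vertex_attr(net$graph))
})

test_that("network exports round-trip and degrade gracefully when empty", {
  set.seed(65)
  nodes <- metabolite_nodes(c("a", "b", "c"),
                            fingerprints = list(random_fp(64, 20),
                                                random_fp(64, 20),
                                                random_fp(64, 20)))
  nodes$fingerprint[[2]] <- nodes$fingerprint[[1]]
  net <- build_network(nodes, data.frame(id_a = "a", id_b = "c"))
  d <- data.frame(feature_id = c("a", "b"), fold_change = c(2, 0.5),
                  p_value = c(0.01, 0.01))
  net <- attach_attributes(net, d)
  prefix <- file.path(withr::local_tempdir(), "net")
  files <- export_network(net, prefix, format = "all")
  sif <- readLines(paste0(prefix, ".sif"))
  expect_length(sif, 2)
  node_tab <- read.delim(paste0(prefix, ".nodes.tsv"))
  expect_equal(nrow(node_tab), 3)
  expect_true("color_class" %in% names(node_tab))

  back <- read_network_graphml(paste0(prefix, ".graphml"))
  expect_setequal(back$nodes$id, nodes$id)
  expect_equal(network_edges(back)[, c("from", "to", "type")],
               network_edges(net)[, c("from", "to", "type")])
  expect_equal(network_edges(back)$tanimoto_score,
               network_edges(net)$tanimoto_score)

  expect_error(export_network(net, prefix, format = "gexf"), "supported")

  # empty network still writes valid files
  set.seed(66)
  lonely <- metabolite_nodes("solo", fingerprints = list(random_fp(64, 10)))
  empty_net <- build_network(lonely, NULL)
  prefix2 <- file.path(withr::local_tempdir(), "empty")
  export_network(empty_net, prefix2, format = "all")
  expect_length(readLines(paste0(prefix2, ".sif")), 0)
  back2 <- read_network_graphml(paste0(prefix2, ".graphml"))
  expect_equal(igraph::ecount(back2$graph), 0)
})

test_that("node metadata and reaction pairs load from packaged TSVs", {
  meta <- system.file("extdata", "example_metabolites_synthetic.tsv",
                      package = "lipidmapp")
  rp <- system.file("extdata", "example_rpairs_synthetic.tsv",
                    package = "lipidmapp")
  nodes <- read_metabolite_nodes(meta)
  expect_s3_class(nodes, "metabolite_nodes")
  expect_true(all(lengths(nodes$fingerprint) > 0))
  net <- build_network(nodes, read_rpair_table(rp))
  ed <- network_edges(net)
  expect_equal(sum(ed$type == "rpair"), 6)
  # class templates create within-class similarity edges
  expect_gt(sum(ed$type == "tanimoto"), 0)
})

test_that("SMILES-derived fingerprints separate chemical families", {
  smi <- c(ala = "CC(N)C(=O)O", abu = "CCC(N)C(=O)O",
           benzene = "c1ccccc1")
  fps <- fingerprint_from_smiles(smi)
  expect_length(fps, 3)
  expect_gt(tanimoto(fps$ala, fps$abu), tanimoto(fps$ala, fps$benzene))
})
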