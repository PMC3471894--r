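# End-to-end orchestration of the synthetic study scenario: library
# generation, spectrum simulation and annotation, normalization,
# ordination, differential statistics, network mapping and export, with
# a run manifest (seed, config hash, file digests, per-stage timing).

#' Run the full pipeline on the packaged scenario
#'
#' Executes generate-library, simulate, annotate, normalize, ordinate
#' (PCA and PLS-DA on the infusion lipid fingerprint), differential
#' statistics (mESC vs m15 on the chromatography tables), network
#' construction and export, writing all intermediates as plain-text
#' files plus a JSON run manifest. Any stage failure aborts with the
#' stage name.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Integer master seed.
#' @param scenario Scenario list as from [stemcell_scenario()]; defaults
#'   to `stemcell_scenario(seed)`.
#' @param n_spectra Number of synthetic MS/MS spectra to annotate.
#' @param rpairs Reaction-pair table; `NULL` aborts the network stage
#'   (set `rpairs = scenario$rpairs` implicitly by default).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(outdir, seed = 20121015L,
                         scenario = stemcell_scenario(seed),
                         n_spectra = 100,
                         rpairs = scenario$rpairs) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "lipidmapp",
                   version = as.character(utils::packageVersion("lipidmapp")),
                   seed = as.integer(seed),
                   stages = list(), files = list())
  t_total <- Sys.time()
  stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<-
      list(seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    res
  }
  out <- function(f) file.path(outdir, f)

  library <- stage("generate-library", function() {
    lib <- enumerate_library()
    write_library(lib, out("library.msp"))
    lib
  })

  sim <- stage("simulate", function() {
    sim <- simulate_spectra(library, n_spectra = n_spectra,
                            seed = scenario$seed + 10L)
    write_mgf(sim$spectra, out("spectra.mgf"))
    write_truth(sim$truth, out("spectra_truth.tsv"))
    tabs <- list(infusion = simulate_table(scenario$lipid_infusion),
                 lc = simulate_table(scenario$lipid_lc),
                 gc = simulate_table(scenario$primary_gc))
    for (nm in names(tabs))
      write_feature_table(tabs[[nm]], out(paste0("table_", nm, "_raw.tsv")))
    c(sim, tabs)
  })

  stage("annotate", function() {
    ann <- annotate_spectra(sim$spectra, library)
    write_annotations(ann, out("annotations.tsv"))
  })

  norm <- stage("normalize", function() {
    tabs <- lapply(sim[c("infusion", "lc", "gc")], normalize_total_intensity)
    for (nm in names(tabs))
      write_feature_table(tabs[[nm]], out(paste0("table_", nm, "_normalized.tsv")))
    tabs
  })

  stage("merge", function() {
    merged <- merge_platforms(list(norm$lc, norm$gc))
    write_feature_table(merged, out("table_merged.tsv"))
  })

  stage("ordinate", function() {
    fit_pca <- pca(norm$infusion, n_components = 2)
    write_ordination(fit_pca, out("pca_scores.tsv"), out("pca_loadings.tsv"))
    fit_pls <- pls_da(norm$infusion, n_components = 2)
    write_ordination(fit_pls, out("plsda_scores.tsv"), out("plsda_loadings.tsv"))
  })

  diff <- stage("stats", function() {
    d <- rbind(differential_table(norm$lc, "mESC", "m15"),
               differential_table(norm$gc, "mESC", "m15"))
    write_differential(d, out("differential_mESC_vs_m15.tsv"))
    d
  })

  stage("network", function() {
    if (is.null(rpairs)) stop("no reaction-pair table supplied")
    net <- build_network(scenario$nodes, rpairs, threshold = 700)
    net <- attach_attributes(net, diff)
    export_network(net, out("network_mESC_vs_m15"), format = "all")
  })

  manifest$files <- as.list(tools::md5sum(
    list.files(outdir, full.names = TRUE, pattern = "\\.(tsv|msp|mgf|graphml|sif)$")))
  names(manifest$files) <- basename(names(manifest$files))
  manifest$total_seconds <- round(as.numeric(Sys.time() - t_total,
                                             units = "secs"), 3)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
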