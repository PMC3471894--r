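# Synthetic-data generation for end-to-end exercise of the pipeline:
# multi-group intensity tables with configurable per-feature group
# effects under multiplicative log-normal noise, noisy MS/MS spectra
# drawn from an in-silico library with truth labels, and a packaged
# three-cell-type scenario (fibroblast m15, mESC, iPSC) with metabolite
# metadata and a toy reaction-pair table.

#' Scenario configuration for table simulation
#'
#' @param groups Named integer vector of replicate counts per group,
#'   e.g. `c(m15 = 3, mESC = 3, iPSC = 3)`; all counts >= 2.
#' @param effects Data frame with columns `feature_id`, `base`
#'   (base intensity > 0), `cv` (coefficient of variation of the
#'   multiplicative log-normal noise, >= 0), and one multiplier column
#'   (> 0) per group.
#' @param platform Platform tag for the generated table.
#' @param seed Integer seed; recorded in the config and used by
#'   [simulate_table()].
#' @return A `scenario_config`.
#' @export
scenario_config <- function(groups, effects, platform = "nanoESI",
                            seed = 1L) {
  if (is.null(names(groups)) || any(groups < 2))
    stop("groups must be a named vector with counts >= 2")
  needed <- c("feature_id", "base", "cv", names(groups))
  missing_cols <- setdiff(needed, names(effects))
  if (length(missing_cols) > 0)
    stop("effects is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(effects$base <= 0)) stop("base intensities must be > 0")
  if (any(effects$cv < 0)) stop("cv must be >= 0")
  if (any(as.matrix(effects[, names(groups)]) <= 0))
    stop("group multipliers must be > 0")
  structure(list(groups = groups, effects = effects, platform = platform,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a grouped intensity table
#'
#' Each measurement is `base * multiplier[group] * exp(eps)` with
#' `eps ~ Normal(0, sigma)` and `sigma = sqrt(log(1 + cv^2))`, so the
#' noise is multiplicative log-normal with the configured coefficient
#' of variation and all values stay positive. Deterministic under the
#' config seed.
#'
#' @param config A `scenario_config`.
#' @return A `feature_table` with samples named `<group>_<replicate>`.
#' @export
simulate_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  eff <- config$effects
  groups <- config$groups
  sample_group <- rep(names(groups), groups)
  sample_ids <- unlist(lapply(names(groups), function(g)
    paste0(g, "_", seq_len(groups[[g]]))))
  n <- length(sample_ids); p <- nrow(eff)
  sigma <- sqrt(log(1 + eff$cv^2))
  m <- matrix(0, n, p, dimnames = list(sample_ids, eff$feature_id))
  for (j in seq_len(p)) {
    mu <- eff$base[j] * unlist(eff[j, sample_group])
    m[, j] <- mu * exp(stats::rnorm(n, 0, sigma[j]))
  }
  feature_table(m, group = sample_group, platform = config$platform,
                sample_ids = sample_ids)
}

#' Simulate noisy MS/MS spectra from a library, with truth labels
#'
#' Each spectrum is derived from one library entry: the precursor is
#' jittered by `Normal(0, precursor_sd_mda)` mDa, fragment m/z by
#' `Normal(0, fragment_sd_da)` Da, fragment intensities are perturbed
#' by log-normal noise with CV `intensity_cv`, and fragments are
#' dropped independently with probability `dropout`.
#'
#' @param library A non-empty `lipid_library`.
#' @param n_spectra Number of spectra; entries are sampled uniformly
#'   with replacement (default: one spectrum per entry, in order).
#' @param precursor_sd_mda Precursor jitter SD in milli-Dalton.
#' @param fragment_sd_da Fragment jitter SD in Dalton.
#' @param intensity_cv Fragment intensity CV.
#' @param dropout Per-fragment dropout probability.
#' @param instrument_mode Instrument tag for the generated spectra.
#' @param seed Integer seed.
#' @return List with `spectra` (list of `spectrum_record`) and `truth`
#'   (data frame `spectrum_id`, `true_name`, `true_chains`, `true_adduct`).
#' @export
simulate_spectra <- function(library, n_spectra = length(library),
                             precursor_sd_mda = 0.5, fragment_sd_da = 0.005,
                             intensity_cv = 0.2, dropout = 0.1,
                             instrument_mode = "qtof", seed = 1L) {
  stopifnot(length(library) > 0, precursor_sd_mda >= 0, fragment_sd_da >= 0,
            dropout >= 0, dropout <= 1)
  set.seed(seed)
  picks <- if (n_spectra == length(library)) seq_along(library) else
    sample.int(length(library), n_spectra, replace = TRUE)
  spectra <- vector("list", length(picks))
  truth <- data.frame(spectrum_id = character(length(picks)),
                      true_name = character(length(picks)),
                      true_chains = character(length(picks)),
                      true_adduct = character(length(picks)),
                      stringsAsFactors = FALSE)
  sigma_int <- sqrt(log(1 + intensity_cv^2))
  for (k in seq_along(picks)) {
    e <- library[[picks[k]]]
    keep <- stats::runif(nrow(e$fragments)) >= dropout
    fr <- e$fragments[keep, , drop = FALSE]
    frag <- data.frame(
      mz = fr$mz + stats::rnorm(nrow(fr), 0, fragment_sd_da),
      intensity = fr$relative_intensity *
        exp(stats::rnorm(nrow(fr), 0, sigma_int)))
    id <- sprintf("synthetic_%04d", k)
    spectra[[k]] <- spectrum_record(
      id, e$precursor_mz + stats::rnorm(1, 0, precursor_sd_mda / 1000),
      frag, instrument_mode = instrument_mode)
    truth$spectrum_id[k] <- id
    truth$true_name[k] <- e$species$short_name
    truth$true_chains[k] <- paste(vapply(e$species$chains, chain_label,
                                         character(1)), collapse = "/")
    truth$true_adduct[k] <- e$species$adduct
  }
  list(spectra = spectra, truth = truth)
}

# Deterministic class-templated fingerprints: members of one chemical
# class share most template bits (pairwise Tanimoto ~ 0.8), members of
# different classes share almost none (~ 0.1).
class_fingerprints <- function(class_of, nbits = 1024, template_bits = 140,
                               flip = 8, seed = 1L) {
  set.seed(seed)
  classes <- unique(class_of)
  templates <- lapply(classes, function(cl)
    sort(sample.int(nbits, template_bits)))
  names(templates) <- classes
  out <- lapply(seq_along(class_of), function(i) {
    tpl <- templates[[class_of[i]]]
    drop_bits <- sample(tpl, flip)
    add_bits <- sample(setdiff(seq_len(nbits), tpl), flip)
    fingerprint(c(setdiff(tpl, drop_bits), add_bits), nbits = nbits)
  })
  names(out) <- names(class_of)
  out
}

# Lipid effect panel shared by the infusion and LC configurations.
# Multipliers encode the qualitative study pattern: polyunsaturated PCs
# (>= 3 double bonds) elevated in pluripotent cells (PC 36:3 at the
# reported +53% in mESC), mono/di-unsaturated PCs and 1-3 double-bond
# PEs reduced (PE 36:3 at the reported -33% in mESC), lyso species
# reduced in iPSC only, sphingomyelins and an abundant saturated pool
# unchanged.
lipid_effect_panel <- function(cv) {
  e <- function(id, base, mESC, iPSC, chem_class)
    data.frame(feature_id = id, base = base, cv = cv, m15 = 1,
               mESC = mESC, iPSC = iPSC, chem_class = chem_class,
               stringsAsFactors = FALSE)
  rbind(
    # stable abundant pool
    e("PC 30:0", 500, 1, 1, "PC"), e("PC 32:0", 800, 1, 1, "PC"),
    e("SM 34:1", 400, 1, 1, "SM"), e("SM 36:2", 250, 1, 1, "SM"),
    e("SM 42:2", 150, 1, 1, "SM"),
    e("TG 52:2", 350, 1, 1, "TG"), e("TG 54:3", 300, 1, 1, "TG"),
    e("TG 50:1", 250, 1, 1, "TG"),
    # polyunsaturated PCs: up in pluripotent cells, slightly stronger in
    # mESC (the stem types differ far less than either does from m15)
    e("PC 34:3", 120, 1.5, 1.44, "PC"),
    e("PC 36:3", 300, 1.53, 1.46, "PC"),
    e("PC 36:4", 350, 1.5, 1.44, "PC"),
    e("PC 38:4", 200, 1.5, 1.44, "PC"),
    e("PC 38:5", 100, 1.55, 1.48, "PC"),
    e("PC 38:6", 150, 1.5, 1.44, "PC"),
    e("PC 40:6", 80, 1.45, 1.39, "PC"),
    e("plasmenyl-PC 36:4", 90, 1.5, 1.44, "plasmenyl-PC"),
    e("plasmenyl-PC 38:5", 60, 1.5, 1.44, "plasmenyl-PC"),
    # mono/di-unsaturated PCs: down in pluripotent cells
    e("PC 32:1", 250, 0.75, 0.77, "PC"), e("PC 32:2", 120, 0.75, 0.77, "PC"),
    e("PC 34:1", 600, 0.75, 0.77, "PC"), e("PC 34:2", 400, 0.75, 0.77, "PC"),
    e("PC 36:1", 150, 0.78, 0.8, "PC"), e("PC 36:2", 300, 0.75, 0.77, "PC"),
    e("plasmenyl-PC 34:1", 70, 0.8, 0.82, "plasmenyl-PC"),
    # highly unsaturated PEs: modest increase
    e("PE 38:4", 180, 1.3, 1.27, "PE"), e("PE 40:6", 90, 1.3, 1.27, "PE"),
    e("PE 38:6", 100, 1.1, 1.1, "PE"),
    e("plasmenyl-PE 38:5", 70, 1.35, 1.32, "plasmenyl-PE"),
    # 1-3 double-bond PEs: down in pluripotent cells
    e("PE 34:1", 200, 0.7, 0.72, "PE"), e("PE 34:2", 150, 0.7, 0.72, "PE"),
    e("PE 36:1", 90, 0.72, 0.74, "PE"), e("PE 36:2", 250, 0.7, 0.72, "PE"),
    e("PE 36:3", 220, 0.67, 0.7, "PE"),
    e("plasmenyl-PE 34:1", 60, 0.7, 0.72, "plasmenyl-PE"),
    e("plasmenyl-PE 36:2", 80, 0.72, 0.74, "plasmenyl-PE"),
    # lyso species: reduced in both stem types, lower still in iPSC
    e("lyso-PC 16:0", 50, 0.85, 0.68, "lyso-PC"),
    e("lyso-PC 18:0", 40, 0.85, 0.68, "lyso-PC"),
    e("lyso-PC 18:1", 35, 0.82, 0.68, "lyso-PC"),
    e("lyso-PE 16:0", 25, 0.85, 0.7, "lyso-PE"),
    e("lyso-PE 18:0", 20, 0.85, 0.7, "lyso-PE"),
    e("lyso-PE 18:1", 20, 0.82, 0.7, "lyso-PE"),
    # minor neutral classes
    e("DG 34:1", 60, 1.1, 1.1, "DG"), e("DG 36:2", 50, 1.1, 1.1, "DG"),
    e("PS 36:1", 120, 1, 1, "PS"), e("PS 38:4", 80, 1.05, 1.05, "PS"),
    e("acylcarnitine 16:0", 30, 1, 1, "acylcarnitine")
  )
}

# Primary-metabolism panel (GC-TOF-like): broad amino acid decrease in
# pluripotent cells (lower still in iPSC), unchanged carbohydrates,
# hydroxy acids, citric-acid-cycle members and free fatty acids, and
# targeted polyamine/purine changes in iPSC.
primary_effect_panel <- function(cv) {
  e <- function(id, base, mESC, iPSC, chem_class)
    data.frame(feature_id = id, base = base, cv = cv, m15 = 1,
               mESC = mESC, iPSC = iPSC, chem_class = chem_class,
               stringsAsFactors = FALSE)
  aa <- c(alanine = 500, glycine = 450, serine = 300, threonine = 200,
          valine = 250, leucine = 280, isoleucine = 180, proline = 220,
          phenylalanine = 150, tyrosine = 120, methionine = 90,
          glutamine = 400)
  rbind(
    do.call(rbind, lapply(names(aa), function(a)
      e(a, aa[[a]], 0.65, 0.55, "amino acid"))),
    e("glucose", 600, 1, 1, "carbohydrate"),
    e("fructose", 200, 1, 1, "carbohydrate"),
    e("glucose-6-phosphate", 150, 1, 1, "carbohydrate"),
    e("ribose-5-phosphate", 80, 1, 1, "carbohydrate"),
    e("lactate", 700, 1, 1, "hydroxy acid"),
    e("citrate", 300, 1, 1, "hydroxy acid"),
    e("succinate", 250, 1, 0.85, "hydroxy acid"),
    e("fumarate", 120, 1, 1, "hydroxy acid"),
    e("malate", 200, 1, 1, "hydroxy acid"),
    e("palmitate", 250, 1, 1, "fatty acid"),
    e("stearate", 200, 1, 1, "fatty acid"),
    e("oleate", 180, 1, 1, "fatty acid"),
    e("putrescine", 100, 0.95, 0.55, "polyamine"),
    e("ornithine", 120, 1, 0.6, "polyamine"),
    e("5-methylthioadenosine", 60, 1.1, 0.7, "nucleoside"),
    e("xanthine", 70, 1, 1.3, "nucleoside"),
    e("inosine-5-phosphate", 90, 1, 0.7, "nucleoside"),
    e("phosphoethanolamine", 150, 1.4, 1.35, "phospholipid precursor")
  )
}

# Toy reaction-pair table over the scenario metabolites (KEGG
# RPAIR-shaped: substrate-product pairs of enzymatic reactions).
scenario_rpairs <- function() {
  rp <- function(a, b) data.frame(id_a = a, id_b = b, stringsAsFactors = FALSE)
  out <- rbind(
    rp("serine", "glycine"), rp("phenylalanine", "tyrosine"),
    rp("threonine", "glycine"), rp("valine", "leucine"),
    rp("glutamine", "proline"), rp("methionine", "5-methylthioadenosine"),
    rp("ornithine", "putrescine"), rp("putrescine", "5-methylthioadenosine"),
    rp("glucose", "glucose-6-phosphate"),
    rp("glucose-6-phosphate", "ribose-5-phosphate"),
    rp("glucose-6-phosphate", "fructose"),
    rp("citrate", "succinate"), rp("succinate", "fumarate"),
    rp("fumarate", "malate"), rp("malate", "citrate"),
    rp("lactate", "glucose"),
    rp("inosine-5-phosphate", "xanthine"),
    rp("phosphoethanolamine", "PE 34:1"),
    rp("PE 36:3", "PC 36:3"), rp("PE 36:2", "PC 36:2"),
    rp("PE 34:1", "PC 34:1"),
    rp("PC 34:1", "lyso-PC 16:0"), rp("PE 34:1", "lyso-PE 16:0"),
    rp("palmitate", "acylcarnitine 16:0"),
    rp("DG 34:1", "PC 34:1"), rp("DG 36:2", "TG 52:2")
  )
  out$rpair_id <- sprintf("RP%05d", seq_len(nrow(out)))
  out
}

#' Packaged three-cell-type study scenario
#'
#' A self-contained configuration emulating a replicated three-group
#' design (fibroblast m15, mESC, iPSC) across platforms: a
#' direct-infusion lipid fingerprint table (3 replicates/group, 10% CV),
#' a chromatography lipid table (6 replicates/group, 5% CV), a
#' primary-metabolism table (6 replicates/group, 5% CV), metabolite
#' metadata with class-templated fingerprints, and a toy reaction-pair
#' table. The embedded effects reproduce the qualitative pattern of the
#' emulated study: pluripotent cells far from fibroblasts with mESC and
#' iPSC nearly overlapping; polyunsaturated PCs up in pluripotent cells
#' (PC 36:3 at +53% in mESC); 1-3 double-bond PEs down (PE 36:3 at -33%
#' in mESC); amino acids down in pluripotent cells and lower still in
#' iPSC.
#'
#' @param seed Integer master seed; per-table seeds are derived from it.
#' @return List with `scenario_config`s `lipid_infusion`, `lipid_lc`,
#'   `primary_gc`, plus `nodes` (a `metabolite_nodes` data frame) and
#'   `rpairs` (reaction-pair data frame), and `seed`.
#' @export
stemcell_scenario <- function(seed = 20121015L) {
  seed <- as.integer(abs(seed) %% 2e9)  # leave headroom for derived seeds
  lipids <- lipid_effect_panel(cv = 0.10)
  lipids_lc <- lipid_effect_panel(cv = 0.05)
  primary <- primary_effect_panel(cv = 0.05)
  cfg_inf <- scenario_config(c(m15 = 3, mESC = 3, iPSC = 3),
                             lipids[, setdiff(names(lipids), "chem_class")],
                             platform = "nanoESI", seed = seed + 1L)
  cfg_lc <- scenario_config(c(m15 = 6, mESC = 6, iPSC = 6),
                            lipids_lc[, setdiff(names(lipids_lc), "chem_class")],
                            platform = "HILIC-QTOF", seed = seed + 2L)
  cfg_gc <- scenario_config(c(m15 = 6, mESC = 6, iPSC = 6),
                            primary[, setdiff(names(primary), "chem_class")],
                            platform = "GC-TOF", seed = seed + 3L)
  all_ids <- c(lipids$feature_id, primary$feature_id)
  all_classes <- c(lipids$chem_class, primary$chem_class)
  fps <- class_fingerprints(stats::setNames(all_classes, all_ids),
                            seed = seed + 4L)
  nodes <- metabolite_nodes(all_ids, fingerprints = fps)
  list(lipid_infusion = cfg_inf, lipid_lc = cfg_lc, primary_gc = cfg_gc,
       nodes = nodes, rpairs = scenario_rpairs(), seed = seed)
}

#' Write simulation truth labels to a sidecar TSV
#' @param truth Truth data frame (e.g. from [simulate_spectra()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
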