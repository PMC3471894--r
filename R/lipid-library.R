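# In-silico lipid MS/MS library generation.
#
# Each lipid class is modeled as a fixed backbone formula plus per-chain
# contributions; species are enumerated over configurable acyl chain pools
# ("computational scaffolds" varying chain length and unsaturation), and
# class-specific fragmentation rules yield template MS/MS spectra.

# Class table. Backbones are the fully hydrolyzed head-group/backbone
# molecules; each esterified acyl chain contributes fatty acid minus water.
#   PC backbone  = glycerophosphocholine       C8H20NO6P
#   PE backbone  = glycerophosphoethanolamine  C5H14NO6P
#   PS backbone  = glycerophosphoserine        C6H14NO8P
#   TG/DG        = glycerol                    C3H8O3
#   SM backbone  = sphingosyl(d18:1)-phosphorylcholine C23H49N2O5P (N-acylated)
#   acylcarnitine backbone = carnitine         C7H15NO3
# Plasmenyl (plasmalogen) classes place an O-alk-1-enyl chain at sn-1:
# relative to the diacyl species of the same C:DB the formula loses one O
# (the vinyl-ether double bond is implicit, not counted in DB totals).
.LIPID_CLASSES <- list(
  "PC"            = list(backbone = c(C = 8,  H = 20, N = 1, O = 6, P = 1), arity = 2, ether_sn1 = FALSE),
  "PE"            = list(backbone = c(C = 5,  H = 14, N = 1, O = 6, P = 1), arity = 2, ether_sn1 = FALSE),
  "plasmenyl-PC"  = list(backbone = c(C = 8,  H = 20, N = 1, O = 6, P = 1), arity = 2, ether_sn1 = TRUE),
  "plasmenyl-PE"  = list(backbone = c(C = 5,  H = 14, N = 1, O = 6, P = 1), arity = 2, ether_sn1 = TRUE),
  "lyso-PC"       = list(backbone = c(C = 8,  H = 20, N = 1, O = 6, P = 1), arity = 1, ether_sn1 = FALSE),
  "lyso-PE"       = list(backbone = c(C = 5,  H = 14, N = 1, O = 6, P = 1), arity = 1, ether_sn1 = FALSE),
  "PS"            = list(backbone = c(C = 6,  H = 14, N = 1, O = 8, P = 1), arity = 2, ether_sn1 = FALSE),
  "SM"            = list(backbone = c(C = 23, H = 49, N = 2, O = 5, P = 1), arity = 1, ether_sn1 = FALSE,
                         base_carbons = 18, base_db = 1),
  "TG"            = list(backbone = c(C = 3,  H = 8,  O = 3), arity = 3, ether_sn1 = FALSE),
  "DG"            = list(backbone = c(C = 3,  H = 8,  O = 3), arity = 2, ether_sn1 = FALSE),
  "acylcarnitine" = list(backbone = c(C = 7,  H = 15, N = 1, O = 3), arity = 1, ether_sn1 = FALSE)
)

.ADDUCTS <- c("[M+H]+", "[M+Na]+")

#' Acyl chain descriptor
#'
#' @param carbons Integer chain length (>= 2).
#' @param double_bonds Integer number of C=C double bonds (>= 0); must not
#'   exceed `floor((carbons - 2) / 2)`.
#' @param ether Logical; `TRUE` for an O-alk-1-enyl (plasmenyl, vinyl-ether)
#'   linkage at sn-1. The vinyl-ether double bond is implicit and not
#'   counted in `double_bonds`.
#' @return An `acyl_chain` object.
#' @export
acyl_chain <- function(carbons, double_bonds = 0, ether = FALSE) {
  carbons <- as.integer(carbons); double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 2) stop("carbons must be an integer >= 2")
  if (is.na(double_bonds) || double_bonds < 0)
    stop("double_bonds must be a non-negative integer")
  if (double_bonds > floor((carbons - 2) / 2))
    stop("double_bonds exceeds floor((carbons - 2)/2) for a ", carbons,
         "-carbon chain")
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 ether = isTRUE(ether)),
            class = "acyl_chain")
}

# "16:0" / "18:1e" notation helpers.
chain_label <- function(chain)
  paste0(chain$carbons, ":", chain$double_bonds, if (chain$ether) "e" else "")

parse_chain <- function(label) {
  ether <- grepl("e$", label)
  label <- sub("e$", "", label)
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("cannot parse chain label: ", label)
  acyl_chain(as.integer(parts[1]), as.integer(parts[2]), ether = ether)
}

# Free fatty acid formula for a (c, d) chain: CcH(2c-2d)O2.
fatty_acid_formula <- function(chain)
  c(C = chain$carbons, H = 2 * chain$carbons - 2 * chain$double_bonds, O = 2)

# Chain contribution to the esterified species:
#   acyl (ester/amide): fatty acid - H2O         = CcH(2c-2d-2)O
#   O-alk-1-enyl:       same minus one further O = CcH(2c-2d-2)
chain_contribution <- function(chain) {
  f <- c(C = chain$carbons, H = 2 * chain$carbons - 2 * chain$double_bonds - 2,
         O = 1)
  if (chain$ether) f <- f[c("C", "H")]
  f
}

#' Assemble a lipid species from class, chains and adduct
#'
#' Builds the elemental formula from the class backbone plus per-chain
#' contributions, the "CLASS C:DB" short name from chain totals (SM totals
#' include the fixed d18:1 sphingoid base), and the adduct precursor m/z.
#'
#' @param lipid_class One of `r paste(names(.LIPID_CLASSES), collapse=", ")`.
#' @param chains List of [acyl_chain()] objects (or "c:d" labels); length
#'   must match the class arity (1 for lyso/SM/acylcarnitine, 2 for
#'   PC/PE/PS/DG and plasmenyl classes, 3 for TG).
#' @param adduct `"[M+H]+"` (default) or `"[M+Na]+"`.
#' @return A `lipid_species` object with fields `lipid_class`, `chains`,
#'   `short_name`, `formula`, `neutral_mass`, `adduct`, `precursor_mz`.
#' @examples
#' sp <- build_species("PC", list("16:0", "20:4"))
#' sp$short_name   # "PC 36:4"
#' @export
build_species <- function(lipid_class, chains, adduct = "[M+H]+") {
  cls <- .LIPID_CLASSES[[lipid_class]]
  if (is.null(cls)) stop("unknown lipid class: ", lipid_class)
  adduct <- match.arg(adduct, .ADDUCTS)
  chains <- lapply(chains, function(ch)
    if (inherits(ch, "acyl_chain")) ch else parse_chain(ch))
  if (length(chains) != cls$arity)
    stop(lipid_class, " requires ", cls$arity, " chain(s), got ",
         length(chains))
  if (cls$ether_sn1) chains[[1]]$ether <- TRUE
  if (!cls$ether_sn1 && any(vapply(chains, `[[`, logical(1), "ether")))
    stop("ether chains are only valid for plasmenyl classes")

  formula <- cls$backbone
  for (ch in chains) formula <- formula_add(formula, chain_contribution(ch))

  total_c <- sum(vapply(chains, `[[`, integer(1), "carbons"))
  total_db <- sum(vapply(chains, `[[`, integer(1), "double_bonds"))
  if (!is.null(cls$base_carbons)) {   # SM: include sphingoid base in totals
    total_c <- total_c + cls$base_carbons
    total_db <- total_db + cls$base_db
  }
  neutral <- monoisotopic_mass(formula)
  prec <- neutral + if (adduct == "[M+H]+") .PROTON_MASS else .SODIUM_CATION_MASS

  structure(list(
    lipid_class = lipid_class,
    chains = chains,
    short_name = paste0(lipid_class, " ", total_c, ":", total_db),
    formula = formula,
    neutral_mass = neutral,
    adduct = adduct,
    precursor_mz = prec
  ), class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(x$short_name, " (",
      paste(vapply(x$chains, chain_label, character(1)), collapse = "/"),
      ") ", x$adduct, "  ", formula_string(x$formula),
      "  m/z ", sprintf("%.4f", x$precursor_mz), "\n", sep = "")
  invisible(x)
}

# ---- fragmentation rules -------------------------------------------------

# Fragment ion masses used by the rules (neutral formula + proton).
.PHOSPHOCHOLINE_ION <- NULL  # computed lazily below via a function

phosphocholine_ion_mz <- function()
  monoisotopic_mass(c(C = 5, H = 14, N = 1, O = 4, P = 1)) + .PROTON_MASS

.NL_PHOSPHOETHANOLAMINE <- c(C = 2, H = 8, N = 1, O = 4, P = 1)
.NL_PHOSPHOSERINE <- c(C = 3, H = 8, N = 1, O = 6, P = 1)
.NL_TRIMETHYLAMINE <- c(C = 3, H = 9, N = 1)

#' Predict class-specific MS/MS fragments for a lipid species
#'
#' Applies fixed per-class fragmentation rules. For protonated
#' PC-family species: the phosphocholine head-group ion m/z 184.0733
#' (intensity 999), the precursor (500), and per acyl chain the neutral
#' losses of the free fatty acid and of its ketene (100 each). PE-family
#' species lose the phosphoethanolamine head (141.0191); PS the
#' phosphoserine head; TG/DG show fatty-acid losses (DG additionally
#' water loss); acylcarnitines the m/z 85.0284 marker. Sodiated species
#' show precursor, trimethylamine loss (choline lipids) and fatty-acid
#' losses. Intensities are fixed templates on a 0-999 scale.
#'
#' @param species A `lipid_species` from [build_species()].
#' @param intensity_template Named numeric overrides for the rule
#'   intensities `c(major = 999, precursor = 500, acyl_loss = 100)`.
#' @return Data frame with columns `mz`, `relative_intensity`, `label`.
#' @export
predict_fragments <- function(species,
                              intensity_template = c(major = 999,
                                                     precursor = 500,
                                                     acyl_loss = 100)) {
  if (!inherits(species, "lipid_species")) stop("species must be a lipid_species")
  it <- c(major = 999, precursor = 500, acyl_loss = 100)
  it[names(intensity_template)] <- intensity_template
  if (length(species$chains) == 0) stop("species has no acyl chains")
  cls <- species$lipid_class
  if (!cls %in% names(.LIPID_CLASSES))
    stop("no fragmentation rules for class: ", cls)
  prec <- species$precursor_mz
  frags <- list()
  add <- function(mz, int, label) {
    frags[[length(frags) + 1L]] <<- list(mz = mz, relative_intensity = int,
                                         label = label)
  }
  add(prec, it[["precursor"]], "precursor")

  choline_family <- cls %in% c("PC", "plasmenyl-PC", "lyso-PC", "SM")
  pe_family <- cls %in% c("PE", "plasmenyl-PE", "lyso-PE")

  if (species$adduct == "[M+H]+") {
    if (choline_family)
      add(phosphocholine_ion_mz(), it[["major"]], "phosphocholine head group")
    if (pe_family)
      add(prec - monoisotopic_mass(.NL_PHOSPHOETHANOLAMINE), it[["major"]],
          "loss of phosphoethanolamine")
    if (cls == "PS")
      add(prec - monoisotopic_mass(.NL_PHOSPHOSERINE), it[["major"]],
          "loss of phosphoserine")
    if (cls == "acylcarnitine")
      add(monoisotopic_mass(c(C = 4, H = 4, O = 2)) + .PROTON_MASS,
          it[["major"]], "acylium marker")
    if (cls == "DG")
      add(prec - monoisotopic_mass(c(H = 2, O = 1)), it[["major"]],
          "loss of water")
    # Per-chain losses for ester-linked (non-ether, non-sphingoid-amide) chains
    if (cls != "SM") {
      loss_int <- if (cls %in% c("TG", "DG")) it[["major"]] else it[["acyl_loss"]]
      for (ch in species$chains) {
        if (ch$ether) next
        lab <- chain_label(ch)
        fa <- monoisotopic_mass(fatty_acid_formula(ch))
        add(prec - fa, loss_int, paste0("loss of ", lab, " fatty acid"))
        if (!cls %in% c("TG", "DG", "acylcarnitine"))
          add(prec - (fa - monoisotopic_mass(c(H = 2, O = 1))),
              it[["acyl_loss"]], paste0("loss of ", lab, " ketene"))
      }
    }
  } else {  # [M+Na]+ — simplified sodiated rule set
    if (choline_family || pe_family)
      add(prec - monoisotopic_mass(.NL_TRIMETHYLAMINE), it[["major"]],
          "loss of trimethylamine")
    for (ch in species$chains) {
      if (ch$ether) next
      add(prec - monoisotopic_mass(fatty_acid_formula(ch)), it[["acyl_loss"]],
          paste0("loss of ", chain_label(ch), " fatty acid"))
    }
  }

  out <- data.frame(
    mz = vapply(frags, `[[`, numeric(1), "mz"),
    relative_intensity = vapply(frags, `[[`, numeric(1), "relative_intensity"),
    label = vapply(frags, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
  # collapse identical-m/z duplicates (e.g. identical chains), keep max int
  out <- out[order(out$mz, -out$relative_intensity), , drop = FALSE]
  out <- out[!duplicated(round(out$mz, 6)), , drop = FALSE]
  out$relative_intensity <- out$relative_intensity / max(out$relative_intensity) * 999
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- enumeration ---------------------------------------------------------

#' Default library configuration
#'
#' Chain pool of common even-chain fatty acids (14:0 to 22:6) applied to
#' all modeled lipid classes, protonated adduct only.
#'
#' @param classes Character vector of lipid classes to enumerate.
#' @param chain_pool Character vector of "c:d" chain labels.
#' @param adducts Character vector of adducts.
#' @return A list usable as `class_config` in [enumerate_library()].
#' @export
default_library_config <- function(classes = names(.LIPID_CLASSES),
                                   chain_pool = c("14:0", "16:0", "16:1",
                                                  "18:0", "18:1", "18:2",
                                                  "18:3", "20:4", "22:6"),
                                   adducts = "[M+H]+") {
  stats::setNames(lapply(classes, function(cl)
    list(chain_pool = chain_pool, adducts = adducts)), classes)
}

#' Read a library configuration from JSON or YAML
#'
#' The file maps class names to objects with `chain_pool` (list of
#' "c:d" labels) and optional `adducts`. YAML input requires the
#' suggested yaml package.
#'
#' @param path Config file path (`.json`, `.yml`/`.yaml`).
#' @return A named list usable as `class_config` in [enumerate_library()].
#' @export
read_library_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lapply(cfg, function(cl) {
    list(chain_pool = unlist(cl$chain_pool),
         adducts = if (is.null(cl$adducts)) "[M+H]+" else unlist(cl$adducts))
  })
}

#' Enumerate an in-silico lipid MS/MS library
#'
#' Produces exactly one [library_entry] per distinct (class, unordered
#' chain multiset, adduct) combination, in deterministic order (class,
#' total carbons, total double bonds, lexicographic chains). For
#' plasmenyl classes the sn-1 ether chain is positionally distinct from
#' the sn-2 acyl chain, so ordered (ether, acyl) pairs are enumerated.
#'
#' @param class_config Named list (class -> list(chain_pool, adducts)),
#'   e.g. from [default_library_config()].
#' @return List of `library_entry` objects (class `lipid_library`).
#' @export
enumerate_library <- function(class_config = default_library_config()) {
  entries <- list()
  for (cl in names(class_config)) {
    cfg <- class_config[[cl]]
    cls <- .LIPID_CLASSES[[cl]]
    if (is.null(cls)) stop("unknown lipid class in config: ", cl)
    pool <- cfg$chain_pool
    if (length(pool) == 0) next
    pool <- sort(unique(pool))
    adducts <- if (is.null(cfg$adducts)) "[M+H]+" else cfg$adducts
    combos <- if (cls$arity == 1) {
      lapply(pool, function(p) list(p))
    } else if (cls$ether_sn1) {
      # ordered: ether sn-1 x acyl sn-2
      do.call(c, lapply(pool, function(a) lapply(pool, function(b) list(a, b))))
    } else {
      # unordered multisets of size arity
      idx <- utils::combn(seq_len(length(pool) + cls$arity - 1), cls$arity)
      apply(idx, 2, function(j) as.list(pool[j - seq_len(cls$arity) + 1]),
            simplify = FALSE)
    }
    for (ad in adducts) {
      for (cmb in combos) {
        sp <- build_species(cl, cmb, adduct = ad)
        entries[[length(entries) + 1L]] <- library_entry(sp)
      }
    }
  }
  # deterministic global order
  if (length(entries) > 0) {
    key <- vapply(entries, function(e) {
      ch <- paste(vapply(e$species$chains, chain_label, character(1)),
                  collapse = "/")
      tot <- sub("^.* ", "", e$species$short_name)
      cd <- as.integer(strsplit(tot, ":")[[1]])
      sprintf("%-16s|%04d|%03d|%s|%s", e$species$lipid_class, cd[1], cd[2],
              ch, e$species$adduct)
    }, character(1))
    entries <- entries[order(key)]
  }
  class(entries) <- "lipid_library"
  entries
}

#' Library entry: a species plus its template spectrum
#'
#' @param species A `lipid_species`.
#' @param fragments Optional fragment data frame; computed with
#'   [predict_fragments()] when omitted.
#' @return A `library_entry` with fields `species`, `precursor_mz`,
#'   `fragments`.
#' @export
library_entry <- function(species, fragments = NULL) {
  if (is.null(fragments)) fragments <- predict_fragments(species)
  stopifnot(nrow(fragments) > 0,
            all(fragments$mz < species$precursor_mz + 0.5))
  structure(list(species = species,
                 precursor_mz = species$precursor_mz,
                 fragments = fragments),
            class = "library_entry")
}

#' @export
print.lipid_library <- function(x, ...) {
  cat("In-silico lipid MS/MS library:", length(x), "entries\n")
  if (length(x) > 0) {
    cls <- table(vapply(x, function(e) e$species$lipid_class, character(1)))
    for (nm in names(cls)) cat("  ", nm, ": ", cls[[nm]], "\n", sep = "")
  }
  invisible(x)
}

entry_id <- function(entry) {
  paste0(entry$species$short_name, " (",
         paste(vapply(entry$species$chains, chain_label, character(1)),
               collapse = "/"), ") ", entry$species$adduct)
}
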