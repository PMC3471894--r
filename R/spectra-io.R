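# Plain-text spectral formats: NIST-dialect MSP for libraries and spectra,
# MGF for experimental spectra. Hand-rolled line parsers; both formats are
# simple key-value records with peak lines.

#' Write an in-silico library to an MSP file
#'
#' NIST dialect: `Name:`, `PRECURSORMZ:`, `PRECURSORTYPE:`, `FORMULA:`,
#' `Comment:` (carries the acyl chain composition), `Num Peaks:` followed
#' by `mz intensity "label"` lines.
#'
#' @param entries A `lipid_library` (list of `library_entry`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    sp <- e$species
    chains <- paste(vapply(sp$chains, chain_label, character(1)),
                    collapse = "/")
    writeLines(c(
      paste0("Name: ", sp$short_name),
      paste0("PRECURSORMZ: ", sprintf("%.4f", e$precursor_mz)),
      paste0("PRECURSORTYPE: ", sp$adduct),
      paste0("FORMULA: ", formula_string(sp$formula)),
      paste0("Comment: class=", sp$lipid_class, "; chains=", chains),
      paste0("Num Peaks: ", nrow(e$fragments))
    ), con)
    writeLines(sprintf("%.4f %d \"%s\"", e$fragments$mz,
                       as.integer(round(e$fragments$relative_intensity)),
                       e$fragments$label), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read an MSP library written by [write_library()]
#'
#' @param path MSP file path.
#' @return A `lipid_library`.
#' @export
read_library <- function(path) {
  lines <- readLines(path)
  entries <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!startsWith(lines[i], "Name:"))
      stop("malformed MSP at line ", i, ": expected 'Name:'")
    fields <- list()
    while (i <= n && nzchar(trimws(lines[i]))) {
      if (grepl("^Num Peaks:", lines[i])) break
      kv <- regmatches(lines[i], regexec("^([^:]+):\\s*(.*)$", lines[i]))[[1]]
      if (length(kv) != 3) stop("malformed MSP header at line ", i)
      fields[[kv[2]]] <- kv[3]
      i <- i + 1L
    }
    if (i > n || !grepl("^Num Peaks:", lines[i]))
      stop("malformed MSP record (missing 'Num Peaks:') near line ", i)
    npk <- as.integer(sub("^Num Peaks:\\s*", "", lines[i]))
    i <- i + 1L
    mz <- numeric(npk); int <- numeric(npk); lab <- character(npk)
    for (k in seq_len(npk)) {
      if (i > n) stop("malformed MSP: truncated peak list at line ", i)
      m <- regmatches(lines[i],
                      regexec("^([0-9.eE+-]+)[ \t]+([0-9.eE+-]+)[ \t]*(\"(.*)\")?\\s*$",
                              lines[i]))[[1]]
      if (length(m) == 0 || is.na(m[1]))
        stop("malformed MSP peak line at line ", i, ": ", lines[i])
      mz[k] <- as.numeric(m[2]); int[k] <- as.numeric(m[3])
      lab[k] <- if (length(m) >= 5) m[5] else ""
      i <- i + 1L
    }
    comment <- fields[["Comment"]]
    cls <- sub("^class=([^;]+);.*$", "\\1", comment)
    chains <- strsplit(sub("^.*chains=", "", comment), "/", fixed = TRUE)[[1]]
    sp <- build_species(cls, as.list(chains),
                        adduct = fields[["PRECURSORTYPE"]])
    frag <- data.frame(mz = mz, relative_intensity = int, label = lab,
                       stringsAsFactors = FALSE)
    entries[[length(entries) + 1L]] <- library_entry(sp, frag)
  }
  class(entries) <- "lipid_library"
  entries
}

#' Export a library as a TSV table
#'
#' One row per fragment with species metadata repeated.
#'
#' @param entries A `lipid_library`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(entries, path) {
  rows <- do.call(rbind, lapply(entries, function(e) {
    data.frame(name = e$species$short_name,
               chains = paste(vapply(e$species$chains, chain_label,
                                     character(1)), collapse = "/"),
               adduct = e$species$adduct,
               formula = formula_string(e$species$formula),
               precursor_mz = e$precursor_mz,
               fragment_mz = e$fragments$mz,
               relative_intensity = e$fragments$relative_intensity,
               label = e$fragments$label,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an experimental spectrum record
#'
#' @param spectrum_id Identifier.
#' @param precursor_mz Precursor m/z (> 0).
#' @param fragments Data frame with columns `mz`, `intensity` (may have
#'   zero rows).
#' @param instrument_mode `"qtof"` or `"iontrap"`.
#' @return A `spectrum_record`.
#' @export
spectrum_record <- function(spectrum_id, precursor_mz, fragments,
                            instrument_mode = c("qtof", "iontrap")) {
  instrument_mode <- match.arg(instrument_mode)
  if (!is.numeric(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be positive")
  if (nrow(fragments) > 0 &&
      (any(!is.finite(fragments$intensity)) || any(fragments$intensity < 0)))
    stop("fragment intensities must be finite and non-negative")
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = precursor_mz,
                 fragments = fragments[, c("mz", "intensity"), drop = FALSE],
                 instrument_mode = instrument_mode),
            class = "spectrum_record")
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `spectrum_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 paste0("PEPMASS=", sprintf("%.5f", s$precursor_mz))), con)
    if (nrow(s$fragments) > 0)
      writeLines(sprintf("%.5f %.2f", s$fragments$mz, s$fragments$intensity),
                 con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read experimental spectra from an MSP file
#'
#' Accepts generic NIST-dialect MSP records (`Name:`, `PRECURSORMZ:`,
#' `Num Peaks:`, peak lines); unlike [read_library()] no library
#' metadata is required.
#'
#' @param path MSP file path.
#' @param instrument_mode Instrument tag to attach to every spectrum.
#' @return List of `spectrum_record`.
#' @export
read_msp_spectra <- function(path, instrument_mode = "qtof") {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!startsWith(lines[i], "Name:"))
      stop("malformed MSP at line ", i, ": expected 'Name:'")
    name <- sub("^Name:\\s*", "", lines[i])
    pre <- NA_real_
    while (i <= n && nzchar(trimws(lines[i])) &&
           !grepl("^Num Peaks:", lines[i])) {
      if (grepl("^PRECURSORMZ:", lines[i]))
        pre <- as.numeric(sub("^PRECURSORMZ:\\s*", "", lines[i]))
      i <- i + 1L
    }
    if (i > n || !grepl("^Num Peaks:", lines[i]))
      stop("malformed MSP record (missing 'Num Peaks:') near line ", i)
    npk <- as.integer(sub("^Num Peaks:\\s*", "", lines[i]))
    i <- i + 1L
    mz <- numeric(npk); int <- numeric(npk)
    for (k in seq_len(npk)) {
      v <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      mz[k] <- as.numeric(v[1]); int[k] <- as.numeric(v[2])
      if (any(is.na(c(mz[k], int[k]))))
        stop("malformed MSP peak line at line ", i)
      i <- i + 1L
    }
    if (is.na(pre)) stop("MSP spectrum '", name, "' lacks PRECURSORMZ")
    spectra[[length(spectra) + 1L]] <-
      spectrum_record(name, pre, data.frame(mz = mz, intensity = int),
                      instrument_mode = instrument_mode)
  }
  spectra
}

#' Read spectra from an MGF file
#'
#' @param path MGF file path.
#' @param instrument_mode Instrument tag to attach to every spectrum.
#' @return List of `spectrum_record`.
#' @export
read_mgf <- function(path, instrument_mode = "qtof") {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    i <- i + 1L
    title <- NULL; pepmass <- NULL; mz <- numeric(0); int <- numeric(0)
    while (i <= n && trimws(lines[i]) != "END IONS") {
      ln <- trimws(lines[i])
      if (startsWith(ln, "TITLE=")) title <- sub("^TITLE=", "", ln)
      else if (startsWith(ln, "PEPMASS="))
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
      else if (nzchar(ln) && !grepl("=", ln, fixed = TRUE)) {
        v <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
        if (length(v) < 2 || any(is.na(v[1:2])))
          stop("malformed MGF peak line at line ", i, ": ", lines[i])
        mz <- c(mz, v[1]); int <- c(int, v[2])
      }
      i <- i + 1L
    }
    if (i > n) stop("malformed MGF: unterminated spectrum at line ", i)
    if (is.null(pepmass)) stop("MGF spectrum without PEPMASS near line ", i)
    if (is.null(title)) title <- paste0("spectrum_", length(spectra) + 1L)
    spectra[[length(spectra) + 1L]] <-
      spectrum_record(title, pepmass,
                      data.frame(mz = mz, intensity = int),
                      instrument_mode = instrument_mode)
    i <- i + 1L
  }
  spectra
}
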