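# Spectral annotation: accurate-mass precursor filtering, instrument
# models (QTOF vs ion trap), sqrt-cosine fragment similarity with greedy
# nearest-m/z peak pairing, and ranked annotation of spectra.

#' Precursor accurate-mass candidate filter
#'
#' Retains exactly the library entries whose precursor m/z lies strictly
#' within `tol_mDa` milli-Dalton of the spectrum precursor. The default
#' reflects accurate-mass QTOF annotation, which requires each candidate
#' to fit the predicted mass with less than 1.5 mDa error.
#'
#' @param spectrum A `spectrum_record`.
#' @param library A `lipid_library`.
#' @param tol_mDa Tolerance in milli-Dalton (> 0), strict inequality.
#' @return Subset of `library` (a `lipid_library`).
#' @export
precursor_candidates <- function(spectrum, library, tol_mDa = 1.5) {
  stopifnot(tol_mDa > 0)
  if (length(library) == 0) return(structure(list(), class = "lipid_library"))
  err <- vapply(library, function(e)
    abs(e$precursor_mz - spectrum$precursor_mz) * 1000, numeric(1))
  out <- library[err < tol_mDa]
  class(out) <- "lipid_library"
  out
}

#' Instrument model for MS/MS fragment observability
#'
#' Ion traps cannot retain fragments below roughly one third of the
#' precursor m/z (the "1/3 mass exclusion rule"), so low-mass ions such
#' as the phosphocholine head group at m/z 184 are unobservable for
#' typical phospholipid precursors. QTOF instruments pass all fragments.
#'
#' @param fragments Fragment data frame with an `mz` column.
#' @param precursor_mz Precursor m/z (> 0).
#' @param instrument_mode `"qtof"` or `"iontrap"`.
#' @return Filtered fragment data frame.
#' @export
apply_instrument_model <- function(fragments, precursor_mz,
                                   instrument_mode = c("qtof", "iontrap")) {
  instrument_mode <- match.arg(instrument_mode)
  stopifnot(precursor_mz > 0)
  if (instrument_mode == "qtof" || nrow(fragments) == 0) return(fragments)
  fragments[fragments$mz >= precursor_mz / 3, , drop = FALSE]
}

#' Fragment similarity score (sqrt-intensity cosine)
#'
#' Peaks are paired greedily by nearest m/z within `frag_tol_Da` (each
#' peak participates in at most one pair), then the cosine of the
#' square-root-transformed intensity vectors is computed over matched
#' pairs and unmatched peaks of both spectra. Identical peak lists score
#' 1; spectra with no matching peaks score 0.
#'
#' @param experimental Data frame with `mz`, `intensity`.
#' @param library_fragments Data frame with `mz` and `relative_intensity`
#'   (or `intensity`).
#' @param frag_tol_Da Fragment m/z tolerance in Dalton (> 0).
#' @return Score in `[0, 1]`.
#' @export
similarity_score <- function(experimental, library_fragments,
                             frag_tol_Da = 0.01) {
  stopifnot(frag_tol_Da > 0)
  int_col <- if ("relative_intensity" %in% names(library_fragments))
    "relative_intensity" else "intensity"
  ne <- nrow(experimental); nl <- nrow(library_fragments)
  if (ne == 0 && nl == 0) stop("similarity undefined: both peak lists empty")
  if (ne == 0 || nl == 0) return(0)
  emz <- experimental$mz; eint <- sqrt(experimental$intensity)
  lmz <- library_fragments$mz; lint <- sqrt(library_fragments[[int_col]])
  # all candidate pairs within tolerance, greedily matched nearest-first
  d <- abs(outer(lmz, emz, "-"))
  cand <- which(d <= frag_tol_Da, arr.ind = TRUE)
  lib_to_exp <- integer(nl)
  if (nrow(cand) > 0) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_exp <- logical(ne)
    for (r in seq_len(nrow(cand))) {
      li <- cand[r, 1]; ei <- cand[r, 2]
      if (lib_to_exp[li] == 0L && !used_exp[ei]) {
        lib_to_exp[li] <- ei
        used_exp[ei] <- TRUE
      }
    }
  }
  if (all(lib_to_exp == 0L)) return(0)
  # vectors over matched pairs + unmatched peaks from both lists
  matched <- which(lib_to_exp > 0L)
  lvec <- c(lint[matched], lint[-matched], rep(0, ne - length(matched)))
  evec <- c(eint[lib_to_exp[matched]], rep(0, nl - length(matched)),
            eint[setdiff(seq_len(ne), lib_to_exp[matched])])
  denom <- sqrt(sum(lvec^2)) * sqrt(sum(evec^2))
  if (denom == 0) return(0)
  min(1, sum(lvec * evec) / denom)
}

#' Annotate MS/MS spectra against an in-silico library
#'
#' For each spectrum, precursor candidates within `tol_mDa` are scored by
#' [similarity_score()] after the library template is filtered through
#' the spectrum's instrument model. Candidates are ranked by score
#' (descending), then absolute precursor error, then short name;
#' annotations with score below `min_score` are dropped.
#'
#' @param spectra List of `spectrum_record`.
#' @param library A non-empty `lipid_library`.
#' @param tol_mDa Precursor tolerance in mDa (default 1.5, accurate-mass
#'   QTOF; use ~500 for unit-resolution ion traps).
#' @param frag_tol_Da Fragment tolerance in Da (default 0.01 for QTOF;
#'   use ~0.5 for ion traps).
#' @param min_score Minimum similarity score to report (default 0.5).
#' @return Data frame with columns `spectrum_id`, `name`, `chains`,
#'   `adduct`, `precursor_error_mDa`, `score`, `rank`.
#' @export
annotate_spectra <- function(spectra, library, tol_mDa = 1.5,
                             frag_tol_Da = 0.01, min_score = 0.5) {
  if (length(library) == 0) stop("library is empty")
  rows <- list()
  for (s in spectra) {
    cands <- precursor_candidates(s, library, tol_mDa)
    if (length(cands) == 0) next
    score <- numeric(length(cands))
    err <- numeric(length(cands))
    for (k in seq_along(cands)) {
      e <- cands[[k]]
      lib_frag <- apply_instrument_model(e$fragments, e$precursor_mz,
                                         s$instrument_mode)
      score[k] <- if (nrow(lib_frag) == 0 || nrow(s$fragments) == 0) 0 else
        similarity_score(s$fragments, lib_frag, frag_tol_Da)
      err[k] <- (e$precursor_mz - s$precursor_mz) * 1000
    }
    keep <- score >= min_score
    if (!any(keep)) next
    cands <- cands[keep]; score <- score[keep]; err <- err[keep]
    nm <- vapply(cands, function(e) e$species$short_name, character(1))
    ord <- order(-score, abs(err), nm)
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = s$spectrum_id,
      name = nm[ord],
      chains = vapply(cands[ord], function(e)
        paste(vapply(e$species$chains, chain_label, character(1)),
              collapse = "/"), character(1)),
      adduct = vapply(cands[ord], function(e) e$species$adduct, character(1)),
      precursor_error_mDa = err[ord],
      score = score[ord],
      rank = seq_along(ord),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0)
    return(data.frame(spectrum_id = character(0), name = character(0),
                      chains = character(0), adduct = character(0),
                      precursor_error_mDa = numeric(0), score = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write annotations to TSV
#' @param annotations Data frame from [annotate_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
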