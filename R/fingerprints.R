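# Structural fingerprints and the Tanimoto coefficient on the 0-1000
# integer scale. Fingerprints are fixed-length bit sets stored as sorted
# integer positions (1-based) with the length in an attribute; they may
# be supplied precomputed (TSV bit strings) or derived from SMILES via
# hashed ChemmineR atom-pair descriptors.

#' Construct a fingerprint from set-bit positions
#'
#' @param bits Integer vector of 1-based set-bit positions.
#' @param nbits Fingerprint length (default 1024).
#' @return A `fingerprint` object.
#' @export
fingerprint <- function(bits, nbits = 1024) {
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) > 0 && (min(bits) < 1 || max(bits) > nbits))
    stop("bit positions must lie in [1, nbits]")
  structure(bits, nbits = as.integer(nbits), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("fingerprint:", length(x), "of", attr(x, "nbits"), "bits set\n")
  invisible(x)
}

#' Parse a fingerprint from a 0/1 character string
#' @param string Character string of 0s and 1s, one per bit.
#' @return A `fingerprint`.
#' @export
parse_fingerprint <- function(string) {
  v <- strsplit(string, "")[[1]]
  if (!all(v %in% c("0", "1"))) stop("fingerprint string must be 0/1 only")
  fingerprint(which(v == "1"), nbits = length(v))
}

#' Serialize a fingerprint to a 0/1 string
#' @param fp A `fingerprint`.
#' @return Character string.
#' @export
fingerprint_string <- function(fp) {
  v <- rep("0", attr(fp, "nbits"))
  v[unclass(fp)] <- "1"
  paste(v, collapse = "")
}

#' Tanimoto similarity on the 0-1000 integer scale
#'
#' `round(1000 * |A intersect B| / |A union B|)` over set bits. Two
#' empty fingerprints have undefined similarity and are rejected.
#'
#' @param fp_a,fp_b `fingerprint` objects of equal length.
#' @return Integer score in 0-1000.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (attr(fp_a, "nbits") != attr(fp_b, "nbits"))
    stop("fingerprint lengths differ")
  a <- unclass(fp_a); b <- unclass(fp_b)
  u <- length(union(a, b))
  if (u == 0) stop("tanimoto undefined: both fingerprints empty")
  as.integer(round(1000 * length(intersect(a, b)) / u))
}

#' Hashed substructure fingerprint from SMILES
#'
#' Computes ChemmineR atom-pair descriptors for each structure and folds
#' them into an `nbits`-long bit set (descriptor modulo `nbits`). This
#' is a hashed substructure fingerprint in the spirit of PubChem-style
#' keys; for exact reproduction of a specific key dictionary, supply
#' precomputed fingerprints instead (see [parse_fingerprint()]).
#' Requires the suggested packages ChemmineR and ChemmineOB.
#'
#' @param smiles Character vector of SMILES strings.
#' @param nbits Fingerprint length (default 1024).
#' @return List of `fingerprint` objects, named after `smiles` names.
#' @export
fingerprint_from_smiles <- function(smiles, nbits = 1024) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("fingerprint_from_smiles requires the ChemmineR package; ",
         "supply precomputed fingerprints instead")
  if (is.null(names(smiles)))
    names(smiles) <- paste0("cmp", seq_along(smiles))
  sdf <- ChemmineR::smiles2sdf(smiles)
  ap <- ChemmineR::sdf2ap(sdf)
  out <- lapply(seq_along(smiles), function(i) {
    desc <- ChemmineR::ap(ap[[i]])
    fingerprint(unique(desc %% nbits) + 1L, nbits = nbits)
  })
  names(out) <- names(smiles)
  out
}
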