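# Monoisotopic atomic masses (IUPAC 2021, rounded to 6 decimals).
# Hard-coded so mass computation has no runtime dependency; the test suite
# checks them against an independently entered higher-precision table.
.ATOMIC_MASS <- c(
  C  = 12.000000,
  H  = 1.007825,
  N  = 14.003074,
  O  = 15.994915,
  P  = 30.973762,
  S  = 31.972071,
  Na = 22.989770
)

# Mass of a proton (H minus one electron); used for [M+H]+ adducts and for
# converting neutral fragment formulas to singly protonated fragment ions.
.PROTON_MASS <- 1.007276
# Sodium cation mass for [M+Na]+ adducts.
.SODIUM_CATION_MASS <- 22.989221
# Neutral mass shift for one additional C=C double bond (loss of H2).
.H2_MASS <- 2 * .ATOMIC_MASS[["H"]]

#' Monoisotopic mass of an elemental formula
#'
#' Sums count-weighted monoisotopic atomic masses over the elements of a
#' formula. Only the elements occurring in the supported lipid and
#' metabolite chemistry (C, H, N, O, P, S, Na) are accepted.
#'
#' @param formula Named numeric vector of non-negative element counts,
#'   e.g. `c(C = 44, H = 80, N = 1, O = 8, P = 1)`. An empty vector has
#'   mass zero.
#' @return Monoisotopic mass in Dalton.
#' @examples
#' monoisotopic_mass(c(H = 2, O = 1)) # water, 18.0106 Da
#' @export
monoisotopic_mass <- function(formula) {
  if (length(formula) == 0) return(0)
  counts <- unlist(formula)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("formula must be a named vector of element counts")
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown) > 0)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("element counts must be non-negative")
  sum(counts * .ATOMIC_MASS[names(counts)])
}

# Add two formulas (named count vectors), 'b' scaled by 'times'.
formula_add <- function(a, b, times = 1) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + times * b
  out[out != 0]
}

# Canonical Hill-order formula string (C, H, then alphabetical).
formula_string <- function(formula) {
  if (length(formula) == 0) return("")
  els <- names(formula)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    n <- formula[[e]]
    if (n == 1) e else paste0(e, n)
  }, character(1)), collapse = "")
}
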