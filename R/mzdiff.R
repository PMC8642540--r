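#' Reference list of m/z differences for redundancy collapsing
#'
#' Mass differences (Da) of common isotope spacings, adduct exchanges and
#' neutral losses used to decide whether two co-eluting, correlated
#' features are chemically redundant (same metabolite). A feature pair
#' matches when the absolute difference of their m/z values is within
#' `tolerance` of one of the listed differences.
#'
#' The shipped list can be replaced by any tibble with `label` and
#' `delta_mz` columns (e.g. read from a TSV).
#'
#' @param tolerance Matching tolerance in Da (default 0.005).
#' @return A tibble with columns `label`, `delta_mz`, and attribute-free
#'   column `tolerance` repeated per row for serialization convenience.
#' @export
default_mzdiff_table <- function(tolerance = 0.005) {
  stopifnot(tolerance > 0)
  tibble::tibble(
    label = c("13C isotope", "+Na/-H", "+K/-H", "+NH4", "-H2O",
              "+HCOOH", "+Cl", "+CH3COOH"),
    delta_mz = c(1.00336, 21.98194, 37.95588, 17.02655, 18.01056,
                 46.00548, 34.96885, 60.02113),
    tolerance = tolerance
  )
}

# TRUE where |mz1 - mz2| matches a listed difference within tolerance
mzdiff_match <- function(dmz, mzdiff) {
  tol <- mzdiff$tolerance[1]
  vapply(dmz, function(d) any(abs(d - mzdiff$delta_mz) <= tol), logical(1))
}
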