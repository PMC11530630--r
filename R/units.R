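# Unit handling for the network JSON dialect. All internal quantities are SI
# (m, s, Pa, m^3/s, Pa.s, m^2/s, m^3, mol/m^3); the reader converts on load.

.unit_tables <- list(
  length = c(m = 1, cm = 1e-2, mm = 1e-3, um = 1e-6, nm = 1e-9),
  time = c(s = 1, ms = 1e-3, min = 60, h = 3600),
  pressure = c(Pa = 1, kPa = 1e3, mbar = 100, bar = 1e5),
  flow_rate = c("m3/s" = 1, "ml/s" = 1e-6, "ul/s" = 1e-9, "nl/s" = 1e-12,
                "ml/min" = 1e-6 / 60, "ul/min" = 1e-9 / 60, "ml/h" = 1e-6 / 3600),
  viscosity = c("Pa.s" = 1, "mPa.s" = 1e-3, cP = 1e-3),
  diffusivity = c("m2/s" = 1, "cm2/s" = 1e-4, "um2/s" = 1e-12),
  volume = c(m3 = 1, l = 1e-3, ml = 1e-6, ul = 1e-9, nl = 1e-12),
  concentration = c("mol/m3" = 1, mM = 1, M = 1e3, "umol/l" = 1e-3),
  area = c(m2 = 1, mm2 = 1e-6, um2 = 1e-12),
  dimensionless = stats::setNames(1, "")
)

#' Convert a JSON quantity to SI
#'
#' A physical value in the network format is either a bare number (taken to be
#' SI) or an object `{"value": x, "unit": "um"}`. This helper applies the unit
#' table for the stated physical dimension.
#'
#' @param x a number or a list with elements `value` and `unit`.
#' @param dimension one of `"length"`, `"time"`, `"pressure"`, `"flow_rate"`,
#'   `"viscosity"`, `"diffusivity"`, `"volume"`, `"concentration"`, `"area"`,
#'   `"dimensionless"`.
#' @param where character, JSON-pointer-like location used in error messages.
#' @return numeric scalar in SI units.
#' @export
parse_quantity <- function(x, dimension, where = "") {
  tab <- .unit_tables[[dimension]]
  if (is.null(tab)) stop("unknown physical dimension '", dimension, "'")
  if (is.numeric(x) && length(x) == 1L) return(as.numeric(x))
  if (is.list(x) && !is.null(x$value) && !is.null(x$unit)) {
    f <- unname(tab[match(as.character(x$unit), names(tab))])
    if (is.na(f)) {
      stop("unknown unit '", x$unit, "' for ", dimension, " at ", where,
           call. = FALSE)
    }
    return(as.numeric(x$value) * f)
  }
  stop("expected a number or {value, unit} object at ", where)
}
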