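#' Unit handling
#'
#' Canonical internal units are hours (time), litres (volume), nanomoles
#' (amount) and nmol/L (concentration). Source tables print flows in L/min;
#' estimated parameters are printed in L/h. All ingestion converts to the
#' canonical set; [convert_units()] performs the conversion and is exact
#' (pure rational factors), so round-trips reproduce printed values.
#'
#' @name units
NULL

.unit_factors <- list(
  # time -> h
  "h"   = 1, "hr" = 1, "hour" = 1,
  "min" = 1 / 60,
  "day" = 24,
  # volume -> L
  "L"  = 1, "l" = 1,
  "mL" = 1e-3, "ml" = 1e-3,
  "uL" = 1e-6,
  # flow -> L/h
  "L/h"   = 1, "l/h" = 1,
  "L/min" = 60, "l/min" = 60,
  "L/day" = 1 / 24,
  # amount -> nmol
  "nmol" = 1, "umol" = 1e3, "mol" = 1e9,
  # concentration -> nmol/L
  "nmol/L" = 1, "nM" = 1,
  "uM" = 1e3, "M" = 1e9,
  # rates -> 1/h
  "1/h" = 1, "1/min" = 60, "1/day" = 1 / 24,
  "1/(M*h)" = 1, "L/h/L" = 1,
  "dimensionless" = 1
)

.unit_class <- function(unit) {
  cls <- c(
    "h" = "time", "hr" = "time", "hour" = "time", "min" = "time", "day" = "time",
    "L" = "volume", "l" = "volume", "mL" = "volume", "ml" = "volume", "uL" = "volume",
    "L/h" = "flow", "l/h" = "flow", "L/min" = "flow", "l/min" = "flow", "L/day" = "flow",
    "nmol" = "amount", "umol" = "amount", "mol" = "amount",
    "nmol/L" = "conc", "nM" = "conc", "uM" = "conc", "M" = "conc",
    "1/h" = "rate", "1/min" = "rate", "1/day" = "rate",
    "1/(M*h)" = "assoc", "L/h/L" = "specific_clearance",
    "dimensionless" = "dimensionless"
  )
  unit[!nzchar(unit)] <- "dimensionless"
  out <- unname(cls[unit])
  if (any(is.na(out))) {
    stop("unknown unit(s): ", paste(unique(unit[is.na(out)]), collapse = ", "))
  }
  out
}

#' Convert values between supported units
#'
#' @param value numeric vector.
#' @param from,to unit strings (e.g. `"L/min"`, `"L/h"`, `"min"`, `"h"`).
#'   Conversion is only permitted within a unit class.
#' @return numeric vector in `to` units.
#' @examples
#' convert_units(0.00099, "L/min", "L/h")  # 0.0594
#' @export
convert_units <- function(value, from, to) {
  if (length(from) != 1L || length(to) != 1L) {
    stop("'from' and 'to' must be single unit strings")
  }
  if (!nzchar(from)) from <- "dimensionless"
  if (!nzchar(to)) to <- "dimensionless"
  if (!identical(.unit_class(from), .unit_class(to))) {
    stop(sprintf("cannot convert '%s' to '%s' (different unit classes)", from, to))
  }
  f_from <- .unit_factors[[from]]
  f_to <- .unit_factors[[to]]
  if (is.null(f_from) || is.null(f_to)) {
    stop("unsupported unit")
  }
  value * f_from / f_to
}

#' Convert a table value to the package's canonical unit for its class
#' @noRd
.to_canonical <- function(value, unit) {
  cls <- .unit_class(unit)
  target <- c(
    time = "h", volume = "L", flow = "L/h", amount = "nmol", conc = "nmol/L",
    rate = "1/h", assoc = "1/(M*h)", specific_clearance = "L/h/L",
    dimensionless = "dimensionless"
  )[[cls]]
  convert_units(value, unit, target)
}
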