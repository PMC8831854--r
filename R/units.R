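#' @keywords internal
"_PACKAGE"

# Exact rational conversion between the two flow units used clinically.
# 1 L/h = 1000 mL / 60 min = 50/3 mL/min; the inverse factor is 3/50.
LH_TO_MLMIN <- 50 / 3
MLMIN_TO_LH <- 3 / 50

FLOW_UNITS <- c("L/h", "mL/min")

crk_error <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "crk_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

#' Convert a flow rate between L/h and mL/min
#'
#' Clearances (kinetic GFR) are conventionally quoted in mL/min while
#' fluid-balance rates are quoted in L/h. The conversion factor is the
#' exact rational 50/3 (L/h to mL/min) or 3/50 (mL/min to L/h), so a
#' round trip is an identity to machine precision.
#'
#' @param value Numeric flow rate(s).
#' @param from,to Unit tags, each one of `"L/h"` or `"mL/min"`.
#' @return Numeric of the same length as `value`, in the `to` unit.
#' @examples
#' convert_flow(3.5, "L/h", "mL/min")   # 58.33...
#' convert_flow(100, "mL/min", "L/h")   # 6
#' @export
convert_flow <- function(value, from, to) {
  if (!is.character(from) || length(from) != 1L || !(from %in% FLOW_UNITS))
    crk_error(sprintf("unknown flow unit '%s'", paste(from, collapse = ",")),
              "crk_invalid_unit")
  if (!is.character(to) || length(to) != 1L || !(to %in% FLOW_UNITS))
    crk_error(sprintf("unknown flow unit '%s'", paste(to, collapse = ",")),
              "crk_invalid_unit")
  stopifnot(is.numeric(value))
  if (from == to) return(value)
  if (from == "L/h") value * LH_TO_MLMIN else value * MLMIN_TO_LH
}
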