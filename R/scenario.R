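#' Define a kinetic creatinine scenario
#'
#' Bundles the six physiological parameters of the one-compartment
#' creatinine mass balance with a linearly changing volume of
#' distribution, `V(t) = V0 + (dV/dt) t`. Validation is strict: a
#' scenario that violates any invariant is rejected, never clamped.
#'
#' @param v0 Volume of distribution (total body water) at `t = 0`, litres.
#'   Must be positive.
#' @param dvdt Constant volume change rate, litres/hour. Negative values
#'   mean net fluid removal (e.g. ultrafiltration on CRRT). Must satisfy
#'   `v0 + dvdt * t > 0` so the volume is not exhausted within the horizon.
#' @param t Elapsed time horizon, hours (non-negative).
#' @param gfrk Kinetic clearance GFR_K, mL/min (non-negative). Understood
#'   broadly as clearance by any route, including extracorporeal (CRRT).
#' @param gen Creatinine generation rate, mg/dL·mL/min (non-negative).
#' @param cr0 Initial serum creatinine concentration, mg/dL (positive).
#' @return An object of class `"kinetic_scenario"`: a named list with the
#'   six fields in the units above.
#' @examples
#' kinetic_scenario(v0 = 42, dvdt = -0.1, t = 24, gfrk = 80, gen = 40, cr0 = 8)
#' @export
kinetic_scenario <- function(v0, dvdt, t, gfrk, gen, cr0) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      crk_error(sprintf("'%s' must be a single finite number", nm),
                "crk_invalid_scenario")
    as.numeric(x)
  }
  v0   <- num1(v0, "v0");   dvdt <- num1(dvdt, "dvdt")
  t    <- num1(t, "t");     gfrk <- num1(gfrk, "gfrk")
  gen  <- num1(gen, "gen"); cr0  <- num1(cr0, "cr0")
  if (v0 <= 0)  crk_error("v0 must be > 0 L", "crk_invalid_scenario")
  if (t < 0)    crk_error("t must be >= 0 h", "crk_invalid_scenario")
  if (gfrk < 0) crk_error("gfrk must be >= 0 mL/min", "crk_invalid_scenario")
  if (gen < 0)  crk_error("gen must be >= 0 mg/dL.mL/min", "crk_invalid_scenario")
  if (cr0 <= 0) crk_error("cr0 must be > 0 mg/dL", "crk_invalid_scenario")
  if (v0 + dvdt * t <= 0)
    crk_error(
      sprintf("volume exhausted within horizon: v0 + dvdt*t = %.4g <= 0 (dvdt must be > -v0/t = %.4g L/h)",
              v0 + dvdt * t, -v0 / t),
      "crk_volume_exhausted")
  structure(
    list(v0 = v0, dvdt = dvdt, t = t, gfrk = gfrk, gen = gen, cr0 = cr0),
    class = "kinetic_scenario")
}

#' @export
print.kinetic_scenario <- function(x, ...) {
  cat("Kinetic creatinine scenario\n")
  cat(sprintf("  V0    : %g L\n", x$v0))
  cat(sprintf("  dV/dt : %g L/h\n", x$dvdt))
  cat(sprintf("  t     : %g h\n", x$t))
  cat(sprintf("  GFR_K : %g mL/min\n", x$gfrk))
  cat(sprintf("  Gen   : %g mg/dL.mL/min\n", x$gen))
  cat(sprintf("  Cr0   : %g mg/dL\n", x$cr0))
  invisible(x)
}

as_scenario <- function(s) {
  if (!inherits(s, "kinetic_scenario"))
    crk_error("expected a 'kinetic_scenario' object", "crk_invalid_scenario")
  s
}

# internal canonical units: all flows in L/h; gen in mg/dL.(L/h) so that
# gen/(gfrk + dvdt) is directly a concentration in mg/dL
gfrk_lh <- function(s) s$gfrk * MLMIN_TO_LH
gen_lh  <- function(s) s$gen * MLMIN_TO_LH

#' Volume of distribution at a given time
#'
#' @param s A [kinetic_scenario()].
#' @param t Time in hours; defaults to the scenario horizon.
#' @return Volume in litres. Errors (class `crk_volume_exhausted`) if the
#'   linear volume model reaches zero or below at `t`.
#' @export
volume_at_time <- function(s, t = s$t) {
  s <- as_scenario(s)
  if (any(t < 0)) crk_error("t must be >= 0 h", "crk_invalid_scenario")
  v <- s$v0 + s$dvdt * t
  if (any(v <= 0))
    crk_error(sprintf("volume exhausted: V(t) <= 0 at t = %g h (dvdt <= -v0/t)",
                      t[which(v <= 0)[1L]]),
              "crk_volume_exhausted")
  v
}

#' Steady-state creatinine concentration
#'
#' The concentration `Gen / (GFR_K + dV/dt)` approached if the clearance
#' and volume rate persisted indefinitely, with the volume rate converted
#' to mL/min so the ratio is a concentration in mg/dL.
#'
#' @param s A [kinetic_scenario()].
#' @param dvdt Volume change rate in L/h; defaults to the scenario's.
#' @return Steady-state creatinine, mg/dL. Errors (class
#'   `crk_no_steady_state`) when `GFR_K + dV/dt <= 0`, in which case no
#'   steady state exists.
#' @export
steady_state_cr <- function(s, dvdt = s$dvdt) {
  s <- as_scenario(s)
  denom <- s$gfrk + convert_flow(dvdt, "L/h", "mL/min")
  if (denom <= 0)
    crk_error("no steady state: GFR_K + dV/dt <= 0 (in mL/min)",
              "crk_no_steady_state")
  s$gen / denom
}
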