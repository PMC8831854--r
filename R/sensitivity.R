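# Analytic partial derivatives of the creatinine trajectory with respect
# to the volume change rate. Writing E = 1 - y for the evolution factor
# (y = (V0/Vt)^(1+g/dv)) and D = gen/(g+dv) - cr0 for the Cr spread,
#   Cr    = cr0 + E D
#   dCr   = E' D + E D'
#   d2Cr  = E'' D + 2 E' D' + E D''
# with E' = y A, E'' = y (A' - A^2),
#   A  = (g/dv^2) log(V0/Vt) + (1 + g/dv) t/Vt
#   A' = -(2g/dv^3) log(V0/Vt) - (2g/dv^2) t/Vt - (1 + g/dv) (t/Vt)^2
#   D' = -gen/(g+dv)^2,  D'' = 2 gen/(g+dv)^3.
# All flows in L/h; gen in mg/dL.(L/h); derivatives in mg/dL per L/h.

sens_terms <- function(v0, g, dv, t) {
  Vt <- v0 + dv * t
  L <- -log1p(dv * t / v0)
  y <- exp((1 + g / dv) * L)
  A <- (g / dv^2) * L + (1 + g / dv) * (t / Vt)
  Ap <- -(2 * g / dv^3) * L - (2 * g / dv^2) * (t / Vt) -
    (1 + g / dv) * (t / Vt)^2
  list(L = L, y = y, A = A, Ap = Ap)
}

d1_eval <- function(v0, g, gen, cr0, dv, t) {
  if (abs(dv) < DERIV_GUARD || abs(g + dv) < DERIV_GUARD) {
    # removable singularity of the analytic form: the trajectory itself
    # is smooth here, so differentiate it numerically instead
    h <- DERIV_GUARD_STEP
    return((cr_eval(v0, g, gen, cr0, dv + h, t) -
            cr_eval(v0, g, gen, cr0, dv - h, t)) / (2 * h))
  }
  w <- sens_terms(v0, g, dv, t)
  D <- gen / (g + dv) - cr0
  Dp <- -gen / (g + dv)^2
  w$y * w$A * D + (1 - w$y) * Dp
}

d2_eval <- function(v0, g, gen, cr0, dv, t) {
  if (abs(dv) < DERIV_GUARD || abs(g + dv) < DERIV_GUARD) {
    h <- DERIV_GUARD_STEP
    return((cr_eval(v0, g, gen, cr0, dv + h, t) -
            2 * cr_eval(v0, g, gen, cr0, dv, t) +
            cr_eval(v0, g, gen, cr0, dv - h, t)) / h^2)
  }
  w <- sens_terms(v0, g, dv, t)
  D <- gen / (g + dv) - cr0
  Dp <- -gen / (g + dv)^2
  Dpp <- 2 * gen / (g + dv)^3
  w$y * (w$Ap - w$A^2) * D + 2 * w$y * w$A * Dp + (1 - w$y) * Dpp
}

check_dvdt_domain <- function(s, dvdt) {
  if (s$t > 0 && any(dvdt <= -s$v0 / s$t))
    crk_error(
      sprintf("dvdt <= -v0/t = %.6g L/h: the trajectory (and derivative) is undefined there",
              -s$v0 / s$t),
      "crk_domain")
  invisible(TRUE)
}

#' First partial derivative of creatinine with respect to the volume rate
#'
#' Analytic `dCr(t)/d(dV/dt)` of the closed-form trajectory, the central
#' quantity of the sensitivity analysis: a positive value is the
#' "positive paradox", where removing fluid faster lowers the later
#' creatinine. Evaluated term-by-term in log space; near the removable
#' singularities `dvdt = 0` and `GFR_K + dvdt = 0` the smooth trajectory
#' is differentiated numerically instead.
#'
#' @param s A [kinetic_scenario()].
#' @param dvdt Volume change rate in L/h at which to evaluate; defaults
#'   to the scenario's. Must exceed `-v0/t`.
#' @return Derivative in mg/dL per L/h.
#' @examples
#' s <- kinetic_scenario(42, -0.1, 24, 80, 40, 8)
#' first_derivative(s)          # about +0.012: the paradox regime
#' @export
first_derivative <- function(s, dvdt = s$dvdt) {
  s <- as_scenario(s)
  check_dvdt_domain(s, dvdt)
  g <- gfrk_lh(s); gen <- gen_lh(s)
  vapply(dvdt, function(dv) d1_eval(s$v0, g, gen, s$cr0, dv, s$t), numeric(1))
}

#' Second partial derivative with respect to the volume rate
#'
#' Analytic `d2Cr(t)/d(dV/dt)^2`; its sign changes bracket the extrema of
#' the first-derivative-versus-volume-rate curve.
#'
#' @inheritParams first_derivative
#' @return Second derivative in mg/dL per (L/h)^2.
#' @export
second_derivative <- function(s, dvdt = s$dvdt) {
  s <- as_scenario(s)
  check_dvdt_domain(s, dvdt)
  g <- gfrk_lh(s); gen <- gen_lh(s)
  vapply(dvdt, function(dv) d2_eval(s$v0, g, gen, s$cr0, dv, s$t), numeric(1))
}

default_fd_step <- function(dvdt) max(1e-6, 1e-6 * abs(dvdt))

#' Finite-difference oracles for the sensitivity derivatives
#'
#' Central differences of [cr_at_time()] (for `fd_first`) and of
#' [first_derivative()] (for `fd_second`), used as independent numerical
#' checks of the analytic derivatives.
#'
#' @inheritParams first_derivative
#' @param h Step in L/h; default `max(1e-6, 1e-6 |dvdt|)`.
#' @return Derivative estimate in mg/dL per L/h (per (L/h)^2 for
#'   `fd_second`). Errors (class `crk_domain`) if the step straddles the
#'   domain boundary `-v0/t`.
#' @export
fd_first <- function(s, dvdt = s$dvdt, h = default_fd_step(dvdt)) {
  s <- as_scenario(s)
  check_dvdt_domain(s, dvdt - h)
  (cr_at_time(s, dvdt = dvdt + h) - cr_at_time(s, dvdt = dvdt - h)) / (2 * h)
}

#' @rdname fd_first
#' @export
fd_second <- function(s, dvdt = s$dvdt, h = default_fd_step(dvdt)) {
  s <- as_scenario(s)
  check_dvdt_domain(s, dvdt - h)
  (first_derivative(s, dvdt + h) - first_derivative(s, dvdt - h)) / (2 * h)
}

#' Numeric derivative of creatinine with respect to kinetic GFR
#'
#' Central finite difference of [cr_at_time()] with respect to `GFR_K`
#' (in mL/min). Used to check numerically the invariant that creatinine
#' always moves opposite to clearance: this derivative is negative for
#' every valid scenario with `t > 0`.
#'
#' @param s A [kinetic_scenario()].
#' @param h Step in mL/min (default `1e-4`).
#' @return Derivative in mg/dL per mL/min.
#' @export
dcr_dgfrk_numeric <- function(s, h = 1e-4) {
  s <- as_scenario(s)
  if (s$gfrk - h < 0)
    crk_error("gfrk - h < 0: shrink the step", "crk_domain")
  up <- kinetic_scenario(s$v0, s$dvdt, s$t, s$gfrk + h, s$gen, s$cr0)
  dn <- kinetic_scenario(s$v0, s$dvdt, s$t, s$gfrk - h, s$gen, s$cr0)
  (cr_at_time(up) - cr_at_time(dn)) / (2 * h)
}
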