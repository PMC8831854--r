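# Regime classification: where the kinetic clearance sits relative to
# the two thresholds Gen/Cr0 + V0/t and 2 V0/t decides the shape of the
# derivative-vs-volume-rate curve and hence whether the derivative can
# ever be positive.

#' Clearance thresholds delimiting the sign regimes
#'
#' The derivative-versus-volume-rate curve changes shape at two
#' clearance values: `t_low = Gen/Cr0 + V0/t` (below it the curve's
#' minimum vanishes and the derivative is always negative) and
#' `t_high = 2 V0/t` (above it the curve has an absolute maximum that
#' can be positive). Both are returned in mL/min; the `V0/t` terms are
#' converted from L/h with the exact factor 50/3.
#'
#' @param gen Creatinine generation rate, mg/dL·mL/min.
#' @param cr0 Initial creatinine, mg/dL (positive).
#' @param v0 Volume of distribution, litres.
#' @param t Time horizon, hours (positive).
#' @return Named numeric `c(t_low = , t_high = )`, mL/min.
#' @examples
#' domain_thresholds(60, 8, 42, 24)   # 36.67 and 58.33 mL/min
#' @export
domain_thresholds <- function(gen, cr0, v0, t) {
  stopifnot(v0 > 0, t > 0, gen >= 0)
  if (!is.numeric(cr0) || cr0 <= 0)
    crk_error("cr0 must be > 0 mg/dL", "crk_invalid_scenario")
  c(t_low = gen / cr0 + (v0 / t) * LH_TO_MLMIN,
    t_high = 2 * (v0 / t) * LH_TO_MLMIN)
}

#' Classify a scenario's potential for a positive derivative
#'
#' Runs the full sign-regime algorithm: computes the clearance
#' thresholds, assigns the scenario to the bottom, middle or top domain,
#' and renders a verdict on whether the derivative of creatinine with
#' respect to the volume rate can be positive. In the top domain the
#' tangency volume rate, benchmark `Cr0`/`Gen` and the positivity
#' interval are computed; the sign of the derivative at the patient's
#' actual volume rate is always reported.
#'
#' Domains use strict inequalities; a clearance exactly on a threshold
#' is assigned to the higher domain and flagged (`on_boundary`). In the
#' middle domain the derivative can only become positive through the
#' diverging left tail as the volume rate approaches `-v0/t`, which is
#' flagged `unrealistic`: such rates would exhaust the body water within
#' the horizon. The algorithm assumes the permissive threshold order
#' `t_low < t_high`. Under a non-permissive order, a clearance below
#' both thresholds is still safely bottom domain (the always-negative
#' claim holds below `t_low`); anything higher is an unsupported-regime
#' error rather than a guess.
#'
#' @param s A [kinetic_scenario()].
#' @return An object of class `"sign_classification"`: list with
#'   `t_low`, `t_high` (mL/min), `permissive`, `domain`
#'   (`"bottom"|"middle"|"top"`), `on_boundary`, `dvdt_star` (L/h or
#'   `NA`), `benchmark_cr0` (mg/dL or `NA`), `benchmark_gen`
#'   (mg/dL·mL/min or `NA`), `can_be_positive`, `unrealistic`,
#'   `positivity` (L/h interval or `numeric(0)`), `sign_at_actual`
#'   (-1, 0 or +1) and `d1_at_actual` (mg/dL per L/h).
#' @examples
#' s <- kinetic_scenario(42, -0.1, 24, 80, 40, 8)
#' classify_scenario(s)
#' @export
classify_scenario <- function(s) {
  s <- as_scenario(s)
  if (s$t <= 0) crk_error("classification needs t > 0", "crk_domain")
  th <- domain_thresholds(s$gen, s$cr0, s$v0, s$t)
  permissive <- th[["t_low"]] < th[["t_high"]]
  if (!permissive && s$gfrk >= min(th))
    crk_error(
      "non-permissive threshold order (Gen/Cr0 + V0/t >= 2 V0/t) with GFR_K above the lower threshold: regime not supported",
      "crk_unsupported_regime")
  domain <- if (s$gfrk < th[["t_low"]]) "bottom"
            else if (s$gfrk < th[["t_high"]]) "middle"
            else "top"
  on_boundary <- s$gfrk %in% th
  out <- list(
    t_low = th[["t_low"]], t_high = th[["t_high"]],
    permissive = permissive, domain = domain, on_boundary = on_boundary,
    dvdt_star = NA_real_, benchmark_cr0 = NA_real_, benchmark_gen = NA_real_,
    can_be_positive = NA, unrealistic = FALSE, positivity = numeric(0),
    sign_at_actual = NA_integer_, d1_at_actual = NA_real_)
  if (domain == "bottom") {
    out$can_be_positive <- FALSE
  } else if (domain == "middle") {
    # only the left tail, diverging to +Inf at dvdt -> -v0/t, can be
    # positive: possible in principle, clinically unrealistic
    out$can_be_positive <- TRUE
    out$unrealistic <- TRUE
  } else {
    star <- tryCatch(tangency_dvdt(s$gfrk, s$v0, s$t),
                     crk_no_tangency = function(e) NA_real_)
    if (!is.na(star)) {
      out$dvdt_star <- star
      out$benchmark_cr0 <- benchmark_cr0(s$gen, s$gfrk, s$v0, s$t, star)
      out$benchmark_gen <- benchmark_gen(s$cr0, s$gfrk, s$v0, s$t, star)
      out$can_be_positive <- s$cr0 > out$benchmark_cr0
    } else {
      # at the marginal clearance GFR_K -> 2 V0/t the tangency point
      # degenerates onto the wall; fall back to the curve's maximum
      cp <- locate_extrema(s)
      out$can_be_positive <- !is.na(cp$max_value) && cp$max_value > 0
    }
    if (out$can_be_positive) out$positivity <- positivity_interval(s)
  }
  d1 <- first_derivative(s)
  out$d1_at_actual <- d1
  out$sign_at_actual <- if (abs(d1) < 1e-12) 0L else as.integer(sign(d1))
  structure(out, class = "sign_classification")
}

#' @export
print.sign_classification <- function(x, ...) {
  cat("Sign classification of dCr/d(dV/dt)\n")
  cat(sprintf("  thresholds : t_low = %.4f, t_high = %.4f mL/min\n",
              x$t_low, x$t_high))
  cat(sprintf("  domain     : %s%s\n", x$domain,
              if (x$on_boundary) " (on boundary)" else ""))
  if (!is.na(x$dvdt_star))
    cat(sprintf("  tangency   : dV/dt* = %.5f L/h; benchmark Cr0 = %.5f mg/dL, Gen = %.5f mg/dL.mL/min\n",
                x$dvdt_star, x$benchmark_cr0, x$benchmark_gen))
  if (length(x$positivity) == 2)
    cat(sprintf("  positive on: (%.5f, %.5f) L/h\n",
                x$positivity[1], x$positivity[2]))
  verdict <- if (isTRUE(x$can_be_positive) && x$unrealistic)
    "derivative can be positive only via the left tail (clinically unrealistic)"
  else if (isTRUE(x$can_be_positive))
    "derivative CAN be positive: the positive paradox is possible"
  else "derivative is always negative"
  cat("  verdict    : ", verdict, "\n", sep = "")
  cat(sprintf("  at actual dV/dt: derivative = %.5g mg/dL per L/h (sign %+d)\n",
              x$d1_at_actual, x$sign_at_actual))
  invisible(x)
}
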