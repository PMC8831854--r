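# Critical points of the first-derivative-vs-volume-rate curve, the
# tangency condition, benchmark Gen / Cr0, positivity intervals and
# trajectory crossing times.
#
# Eliminating the Cr spread D between dCr/d(dV/dt) = 0 and its
# derivative = 0 gives a tangency condition in GFR_K, V0, t and dV/dt
# alone (it contains neither Gen nor Cr0):
#   2 A (1-y)/(g+dv) + A' (1-y) - A^2 (1+y) = 0
# whose root dv* is where the curve's absolute maximum touches the
# x-axis. Back-substituting into dCr/d(dV/dt) = 0 yields the benchmark
# Cr0 for a known Gen, or the benchmark Gen for a known Cr0.

#' Bracketed scalar root finding
#'
#' Thin deterministic wrapper used by all root-finding operations in the
#' package: if `f` does not change sign across `[lower, upper]`, the
#' interval is scanned on a grid for a sign change first; the bracketed
#' root is then refined by Brent's method ([stats::uniroot()]).
#'
#' @param f A scalar function.
#' @param lower,upper Search interval.
#' @param tol Convergence tolerance on the root location (default 1e-10).
#' @param n_scan Grid points used to hunt for a sign change (default 64).
#' @param maxiter Iteration cap (default 200).
#' @return The root, a single numeric. Errors (class `crk_no_root`) when
#'   no sign change can be found in the interval.
#' @examples
#' find_root(function(x) x^2 - 2, 1, 2)   # sqrt(2)
#' @export
find_root <- function(f, lower, upper, tol = 1e-10, n_scan = 64, maxiter = 200) {
  stopifnot(is.function(f), lower < upper)
  fl <- f(lower); fu <- f(upper)
  if (!is.finite(fl) || !is.finite(fu))
    crk_error("f is not finite at the bracket endpoints", "crk_no_root")
  if (fl == 0) return(lower)
  if (fu == 0) return(upper)
  if (sign(fl) * sign(fu) > 0) {
    xs <- seq(lower, upper, length.out = n_scan)
    ys <- vapply(xs, f, numeric(1))
    ok <- which(is.finite(ys[-1]) & is.finite(ys[-n_scan]) &
                  sign(ys[-1]) * sign(ys[-n_scan]) <= 0)
    if (length(ok) == 0)
      crk_error("no sign change of f in the search interval", "crk_no_root")
    lower <- xs[ok[1L]]; upper <- xs[ok[1L] + 1L]
  }
  stats::uniroot(f, c(lower, upper), tol = tol, maxiter = maxiter)$root
}

# tangency condition in canonical units (flows L/h)
tangency_fn <- function(v0, g, dv, t) {
  w <- sens_terms(v0, g, dv, t)
  2 * w$A * (1 - w$y) / (g + dv) + w$Ap * (1 - w$y) - w$A^2 * (1 + w$y)
}

#' Volume rate at which the derivative curve is tangent to the x-axis
#'
#' Solves the simultaneous-zero condition (first and second derivative of
#' creatinine with respect to the volume rate both zero) for the volume
#' change rate. The condition depends only on `GFR_K`, `V0` and `t` --
#' not on `Gen` or `Cr0` -- and is meaningful in the top clearance domain
#' `GFR_K > 2 V0/t` where the derivative curve has an absolute maximum.
#'
#' @param gfrk Kinetic clearance, mL/min.
#' @param v0 Volume of distribution, litres.
#' @param t Time horizon, hours.
#' @param upper Upper end of the search range in L/h (default 0: all
#'   printed tangency roots are negative; widen only deliberately).
#' @return The tangency volume rate `dv*` in L/h. Errors (class
#'   `crk_no_tangency`) when no root exists in `(-v0/t, upper)`.
#' @examples
#' tangency_dvdt(100, 42, 24)   # -0.88928 L/h
#' @export
tangency_dvdt <- function(gfrk, v0, t, upper = 0) {
  stopifnot(v0 > 0, t > 0, gfrk >= 0)
  g <- gfrk * MLMIN_TO_LH
  wall <- -v0 / t
  # geometric grid hugging the wall (the root collapses onto the wall as
  # GFR_K approaches 2 V0/t from above), then refine the first sign change
  delta <- (upper - wall) * 10^seq(-13, 0, length.out = 400)
  xs <- wall + delta[-length(delta)]
  ys <- vapply(xs, function(dv) tangency_fn(v0, g, dv, t), numeric(1))
  ok <- which(is.finite(ys[-1]) & is.finite(ys[-length(ys)]) &
                sign(ys[-1]) * sign(ys[-length(ys)]) <= 0)
  if (length(ok) == 0)
    crk_error("no tangency root in (-v0/t, upper): is GFR_K in the top domain (> 2 V0/t)?",
              "crk_no_tangency")
  i <- ok[1L]
  find_root(function(dv) tangency_fn(v0, g, dv, t), xs[i], xs[i + 1L],
            tol = 1e-12)
}

bench_terms <- function(gfrk, v0, t, dvdt_star) {
  g <- gfrk * MLMIN_TO_LH
  if (v0 + dvdt_star * t <= 0)
    crk_error("dvdt_star <= -v0/t", "crk_domain")
  w <- sens_terms(v0, g, dvdt_star, t)
  list(g = g, y = w$y, A = w$A)
}

#' Benchmark initial creatinine for a tangent maximum
#'
#' Given a generation rate and the tangency volume rate from
#' [tangency_dvdt()], returns the initial creatinine `Cr0` that places
#' the absolute maximum of the derivative curve exactly on the x-axis. A
#' patient whose actual `Cr0` exceeds this benchmark can experience a
#' positive derivative (the paradox); below it the derivative is always
#' negative.
#'
#' @param gen Creatinine generation rate, mg/dL·mL/min.
#' @param gfrk Kinetic clearance, mL/min.
#' @param v0 Volume of distribution, litres.
#' @param t Time horizon, hours.
#' @param dvdt_star Tangency volume rate in L/h (from [tangency_dvdt()];
#'   use it, not the patient's actual rate).
#' @return Benchmark `Cr0`, mg/dL.
#' @examples
#' dv <- tangency_dvdt(100, 42, 24)
#' benchmark_cr0(70, 100, 42, 24, dv)   # 8.03779 mg/dL
#' @export
benchmark_cr0 <- function(gen, gfrk, v0, t, dvdt_star) {
  b <- bench_terms(gfrk, v0, t, dvdt_star)
  gl <- gen * MLMIN_TO_LH
  if (abs(b$y * b$A) < 1e-300)
    crk_error("degenerate tangency: y*A ~ 0", "crk_degenerate_tangency")
  gl / (b$g + dvdt_star) -
    (1 - b$y) * gl / (b$g + dvdt_star)^2 / (b$y * b$A)
}

#' Benchmark generation rate for a tangent maximum
#'
#' The counterpart of [benchmark_cr0()]: given a measured initial
#' creatinine, the generation rate that places the derivative curve's
#' maximum on the x-axis. A patient whose actual `Gen` is below this
#' benchmark can experience a positive derivative. The ratio
#' `benchmark_gen / cr0` (mL/min) is a fixed attribute of
#' `(GFR_K, V0, t)`.
#'
#' @param cr0 Initial creatinine, mg/dL.
#' @inheritParams benchmark_cr0
#' @return Benchmark `Gen`, mg/dL·mL/min.
#' @examples
#' dv <- tangency_dvdt(100, 42, 24)
#' benchmark_gen(8, 100, 42, 24, dv)   # 69.67084 mg/dL.mL/min
#' @export
benchmark_gen <- function(cr0, gfrk, v0, t, dvdt_star) {
  b <- bench_terms(gfrk, v0, t, dvdt_star)
  denom <- b$y * b$A / (b$g + dvdt_star) - (1 - b$y) / (b$g + dvdt_star)^2
  if (abs(denom) < 1e-300)
    crk_error("degenerate tangency: singular denominator",
              "crk_degenerate_tangency")
  (b$y * b$A * cr0 / denom) * LH_TO_MLMIN
}

# grid over the admissible volume-rate range (-v0/t, right]: geometric
# near the left wall, linear elsewhere
dvdt_grid <- function(v0, t, right = 50, n_left = 200, n_right = 200) {
  wall <- -v0 / t
  left <- wall + (v0 / t) * 10^seq(-6, 0, length.out = n_left)
  c(left[-n_left], seq(1e-3, right, length.out = n_right))
}

#' Extrema of the derivative-versus-volume-rate curve
#'
#' Scans the first derivative over the admissible volume-rate range
#' `(-v0/t, +50]` L/h for interior local extrema (which is robust even
#' when the maximum and minimum nearly merge), then refines each as a
#' bracketed root of the second derivative. In the top clearance domain
#' the curve has one absolute maximum followed by one relative minimum;
#' in lower domains one or both are absent, which is encoded as `NA`,
#' not an error.
#'
#' @param s A [kinetic_scenario()].
#' @param right Right end of the scanned range, L/h (default 50).
#' @return An object of class `"critical_points"`: list with
#'   `max_dvdt`, `max_value`, `min_dvdt`, `min_value` (L/h and mg/dL per
#'   L/h; `NA` when absent).
#' @export
locate_extrema <- function(s, right = 50) {
  s <- as_scenario(s)
  if (s$t <= 0) crk_error("extrema need t > 0", "crk_domain")
  xs <- dvdt_grid(s$v0, s$t, right)
  ys <- first_derivative(s, xs)
  n <- length(xs)
  out <- list(max_dvdt = NA_real_, max_value = NA_real_,
              min_dvdt = NA_real_, min_value = NA_real_)
  for (i in seq(2L, n - 1L)) {
    is_max <- ys[i] > ys[i - 1L] && ys[i] > ys[i + 1L]
    is_min <- ys[i] < ys[i - 1L] && ys[i] < ys[i + 1L]
    if (!is_max && !is_min) next
    # a strict interior extremum of d1 brackets a sign change of d2
    r <- find_root(function(dv) second_derivative(s, dv),
                   xs[i - 1L], xs[i + 1L], tol = 1e-12, n_scan = 16)
    v <- first_derivative(s, r)
    if (is_max) {
      if (is.na(out$max_value) || v > out$max_value) {
        out$max_dvdt <- r; out$max_value <- v
      }
    } else if (is.na(out$min_value) || v < out$min_value) {
      out$min_dvdt <- r; out$min_value <- v
    }
  }
  structure(out, class = "critical_points")
}

#' @export
print.critical_points <- function(x, ...) {
  fmt <- function(a, b) {
    if (is.na(a)) "absent\n"
    else sprintf("at dV/dt = %.6g L/h, value %.6g mg/dL per L/h\n", a, b)
  }
  cat("Critical points of dCr/d(dV/dt) vs dV/dt\n")
  cat("  maximum: ", fmt(x$max_dvdt, x$max_value))
  cat("  minimum: ", fmt(x$min_dvdt, x$min_value))
  invisible(x)
}

#' Volume-rate interval on which the derivative is positive
#'
#' When the curve's absolute maximum is positive, the first derivative is
#' positive on a single interval of volume rates around it; this locates
#' the interval endpoints as the two roots of the first derivative
#' bracketing the maximum.
#'
#' @inheritParams locate_extrema
#' @return Numeric of length 2, `c(lo, hi)` in L/h, or `numeric(0)` when
#'   the derivative is never positive (maximum absent or `<= 0`).
#' @export
positivity_interval <- function(s, right = 50) {
  s <- as_scenario(s)
  cp <- locate_extrema(s, right = right)
  if (is.na(cp$max_dvdt) || cp$max_value <= 0) return(numeric(0))
  wall <- -s$v0 / s$t
  lo <- find_root(function(dv) first_derivative(s, dv),
                  wall + (s$v0 / s$t) * 1e-9, cp$max_dvdt,
                  tol = 1e-13, n_scan = 400)
  hi <- find_root(function(dv) first_derivative(s, dv),
                  cp$max_dvdt, right, tol = 1e-13, n_scan = 400)
  c(lo, hi)
}

#' Time at which two trajectories cross
#'
#' For one scenario run under two different volume rates, finds the time
#' in `(0, horizon]` at which the two creatinine trajectories intersect
#' (the trivial intersection at `t = 0` is excluded).
#'
#' @param s A [kinetic_scenario()] supplying `v0`, `gfrk`, `gen`, `cr0`
#'   and the horizon.
#' @param dvdt_a,dvdt_b The two volume rates, L/h.
#' @param horizon Search horizon in hours (default the scenario's `t`).
#' @return Crossing time in hours, or `NA` when the curves do not cross
#'   (including the degenerate case `dvdt_a == dvdt_b`).
#' @export
crossing_time <- function(s, dvdt_a, dvdt_b, horizon = s$t) {
  s <- as_scenario(s)
  if (dvdt_a == dvdt_b) return(NA_real_)
  check_dvdt_domain(s, c(dvdt_a, dvdt_b))
  gap <- function(tt) cr_at_time(s, t = tt, dvdt = dvdt_a) -
    cr_at_time(s, t = tt, dvdt = dvdt_b)
  ts <- seq(1e-3, horizon, length.out = 400)
  gs <- vapply(ts, gap, numeric(1))
  i <- which(sign(gs[-1]) * sign(gs[-length(gs)]) <= 0)
  if (length(i) == 0) return(NA_real_)
  find_root(gap, ts[i[1L]], ts[i[1L] + 1L], tol = 1e-10)
}

#' Time at which the slower trajectory starts to catch up
#'
#' The time maximizing the concentration gap `Cr(t; a) - Cr(t; b)`:
#' before it the gap widens, after it the faster-clearing curve closes
#' in. Located as the root of the gap's time derivative (central finite
#' difference).
#'
#' @inheritParams crossing_time
#' @return Time in hours, or `NA` when there is no interior maximum
#'   (including `dvdt_a == dvdt_b`).
#' @export
catchup_time <- function(s, dvdt_a, dvdt_b, horizon = s$t) {
  s <- as_scenario(s)
  if (dvdt_a == dvdt_b) return(NA_real_)
  check_dvdt_domain(s, c(dvdt_a, dvdt_b))
  gap <- function(tt) cr_at_time(s, t = tt, dvdt = dvdt_a) -
    cr_at_time(s, t = tt, dvdt = dvdt_b)
  h <- 1e-4
  dgap <- function(tt) (gap(tt + h) - gap(tt - h)) / (2 * h)
  ts <- seq(2 * h, horizon - 2 * h, length.out = 400)
  gs <- vapply(ts, dgap, numeric(1))
  i <- which(sign(gs[-1]) * sign(gs[-length(gs)]) <= 0)
  if (length(i) == 0) return(NA_real_)
  find_root(dgap, ts[i[1L]], ts[i[1L] + 1L], tol = 1e-10)
}
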