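# Named clinical fixtures and numeric curve sampling/export.

#' Canonical clinical scenarios
#'
#' A named set of fixtures spanning the regimes of the sensitivity
#' analysis: `aki` (abrupt fall of clearance to 20 mL/min, always-negative
#' derivative); `gen_sweep` (generation rate varied 10-100 at a clearance
#' of 100 mL/min, the family whose Gen = 70 member nearly touches the
#' x-axis); `cr0_sweep` (initial creatinine varied 2-10); `gfrk_sweep`
#' (clearance varied down through both thresholds); `worked` and `crrt`
#' (a septic patient on CRRT, Gen = 40, Cr0 = 8, GFR_K = 80, under
#' ultrafiltration rates of 0.1 and 0.3 L/h respectively -- the positive
#' paradox case).
#'
#' @return A named list. Single scenarios are [kinetic_scenario()]
#'   objects; `*_sweep` entries are lists of scenarios.
#' @examples
#' reference_scenarios()$worked
#' @export
reference_scenarios <- function() {
  sc <- function(gfrk, gen, cr0, dvdt = -0.1)
    kinetic_scenario(v0 = 42, dvdt = dvdt, t = 24,
                     gfrk = gfrk, gen = gen, cr0 = cr0)
  list(
    aki        = sc(gfrk = 20, gen = 100, cr0 = 1),
    gen_sweep  = lapply(seq(10, 100, by = 10),
                        function(g) sc(gfrk = 100, gen = g, cr0 = 8)),
    cr0_sweep  = lapply(c(2, 5, 7, 10),
                        function(c0) sc(gfrk = 100, gen = 60, cr0 = c0)),
    gfrk_sweep = lapply(c(90, 80, 70, 58.34, 57, 50, 36.67, 30),
                        function(g) sc(gfrk = g, gen = 60, cr0 = 8)),
    worked     = sc(gfrk = 80, gen = 40, cr0 = 8, dvdt = -0.1),
    crrt       = sc(gfrk = 80, gen = 40, cr0 = 8, dvdt = -0.3)
  )
}

#' Sample a sensitivity or trajectory curve on a grid
#'
#' Tabulates either the first derivative versus volume rate
#' (`axis = "dvdt"`) or the creatinine trajectory versus time
#' (`axis = "time"`) for one scenario, as a plain numeric table suitable
#' for export.
#'
#' @param s A [kinetic_scenario()].
#' @param axis `"dvdt"` or `"time"`.
#' @param grid Strictly increasing numeric grid: volume rates in L/h
#'   (each `> -v0/t`) or times in hours (each `>= 0`, volume positive).
#' @return An object of class `"curve_sample"`: a data frame with
#'   columns `x` and `y`, with attributes `axis`, `units` (length-2
#'   character) and `scenario` (parameter echo).
#' @examples
#' s <- reference_scenarios()$crrt
#' head(sample_curve(s, "time", seq(0, 24, 0.1)))
#' @export
sample_curve <- function(s, axis = c("dvdt", "time"), grid) {
  s <- as_scenario(s)
  axis <- match.arg(axis)
  if (!is.numeric(grid) || length(grid) < 1L || anyNA(grid))
    crk_error("grid must be numeric and non-empty", "crk_domain")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    crk_error("grid must be strictly increasing", "crk_domain")
  if (axis == "dvdt") {
    check_dvdt_domain(s, grid)
    y <- first_derivative(s, grid)
    units <- c(x = "L/h", y = "mg/dL per L/h")
  } else {
    if (any(grid < 0) || any(s$v0 + s$dvdt * grid <= 0))
      crk_error("time grid outside the admissible domain", "crk_domain")
    y <- cr_at_time(s, t = grid)
    units <- c(x = "h", y = "mg/dL")
  }
  structure(data.frame(x = grid, y = y),
            axis = axis, units = units, scenario = unclass(s),
            class = c("curve_sample", "data.frame"))
}

curve_header <- function(axis, units) {
  xn <- if (axis == "dvdt") "dvdt" else "time"
  yn <- if (axis == "dvdt") "d1" else "cr"
  sprintf("%s (%s),%s (%s)", xn, units[["x"]], yn, units[["y"]])
}

#' Write / read a sampled curve as CSV
#'
#' Comma-separated, LF line endings, '.' decimal separator, one header
#' row carrying unit suffixes in parentheses, values formatted to 10
#' significant digits. `read_curve_csv()` parses a file written by
#' `write_curve_csv()`; the formatted values round-trip exactly.
#'
#' @param curve A [sample_curve()] result.
#' @param path File path.
#' @return `write_curve_csv()` returns `path` invisibly;
#'   `read_curve_csv()` returns a data frame with columns `x` and `y`
#'   and attribute `axis`.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "curve_sample"))
  axis <- attr(curve, "axis")
  lines <- c(curve_header(axis, attr(curve, "units")),
             sprintf("%.10g,%.10g", curve$x, curve$y))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  axis <- if (startsWith(lines[1L], "dvdt")) "dvdt" else "time"
  parts <- strsplit(lines[-1L], ",", fixed = TRUE)
  df <- data.frame(x = as.numeric(vapply(parts, `[[`, "", 1L)),
                   y = as.numeric(vapply(parts, `[[`, "", 2L)))
  attr(df, "axis") <- axis
  df
}
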