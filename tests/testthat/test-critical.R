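test_that("bracketed root finder solves simple and tangency problems", {
  expect_equal(find_root(function(x) x - 2, 0, 5, tol = 1e-12), 2,
               tolerance = 1e-10)
  expect_equal(find_root(function(x) x^2 - 2, 1, 2), sqrt(2),
               tolerance = 1e-9)
  # sign-change hunting on an interval whose endpoints agree in sign
  expect_equal(find_root(function(x) (x - 1) * (x - 9), 0, 5), 1,
               tolerance = 1e-8)
  expect_error(find_root(function(x) x^2 + 1, -5, 5), class = "crk_no_root")
})

test_that("tangency volume rate matches the reference roots", {
  expect_lt(abs(tangency_dvdt(100, 42, 24) - (-0.88928)), 1e-4)
  expect_lt(abs(tangency_dvdt(80, 42, 24) - (-1.43818)), 1e-4)
  # no tangency root outside the top clearance domain
  expect_error(tangency_dvdt(30, 42, 24), class = "crk_no_tangency")
})

test_that("tangency plus benchmark zeroes both derivatives simultaneously", {
  for (p in list(c(100, 42, 24), c(80, 42, 24), c(120, 35, 18))) {
    dv <- tangency_dvdt(p[1], p[2], p[3])
    bc <- benchmark_cr0(70, p[1], p[2], p[3], dv)
    s <- kinetic_scenario(p[2], dv, p[3], p[1], 70, bc)
    expect_lt(abs(first_derivative(s, dv)), 1e-8)
    expect_lt(abs(second_derivative(s, dv)), 1e-8)
  }
})

test_that("benchmark Gen and Cr0 match the reference values", {
  dv1 <- tangency_dvdt(100, 42, 24)
  dv2 <- tangency_dvdt(80, 42, 24)
  expect_lt(abs(benchmark_gen(8, 100, 42, 24, dv1) - 69.67084), 1e-5)
  expect_lt(abs(benchmark_cr0(70, 100, 42, 24, dv1) - 8.03779), 1e-5)
  expect_lt(abs(benchmark_gen(8, 80, 42, 24, dv2) - 78.42), 5e-3)
  expect_lt(abs(benchmark_cr0(40, 80, 42, 24, dv2) - 4.08), 5e-3)
})

test_that("the Gen/Cr0 ratio at tangency is a fixed scenario attribute", {
  dv <- tangency_dvdt(100, 42, 24)
  expect_lt(abs(benchmark_gen(8, 100, 42, 24, dv) / 8 - 8.708), 1e-3)
  # the ratio is the same whichever of Gen/Cr0 is solved for
  for (cr0 in c(2, 8, 11)) {
    bg <- benchmark_gen(cr0, 100, 42, 24, dv)
    expect_equal(bg / cr0, 70 / benchmark_cr0(70, 100, 42, 24, dv),
                 tolerance = 1e-10)
    # round trip: solving back for Cr0 from the benchmark Gen recovers it
    expect_equal(benchmark_cr0(bg, 100, 42, 24, dv), cr0, tolerance = 1e-10)
  }
})

test_that("extrema of the derivative curve are located and classified", {
  s <- kinetic_scenario(42, -0.1, 24, gfrk = 100, gen = 70, cr0 = 8)
  cp <- locate_extrema(s)
  expect_lt(abs(cp$max_value - (-0.0008)), 2e-4)
  expect_false(is.na(cp$min_dvdt))
  expect_lt(cp$max_dvdt, cp$min_dvdt)
  expect_gt(cp$max_value, cp$min_value)
  # roots re-evaluate the defining function to near zero
  expect_lt(abs(second_derivative(s, cp$max_dvdt)), 1e-8)
  expect_lt(abs(second_derivative(s, cp$min_dvdt)), 1e-8)
  # bottom domain: no extrema at all, encoded as absence
  cp2 <- locate_extrema(kinetic_scenario(42, -0.1, 24, 30, 60, 8))
  expect_true(is.na(cp2$max_dvdt) && is.na(cp2$min_dvdt))
  # severe AKI: curve rises monotonically below the axis, no extrema
  cp3 <- locate_extrema(aki_scenario())
  expect_true(is.na(cp3$max_dvdt))
  expect_true(all(first_derivative(aki_scenario(),
                                   seq(-1.5, 5, length.out = 50)) < 0))
  # middle domain: only the minimum survives
  cp4 <- locate_extrema(kinetic_scenario(42, -0.1, 24, 50, 60, 8))
  expect_true(is.na(cp4$max_dvdt))
  expect_false(is.na(cp4$min_dvdt))
})

test_that("raising Gen lowers the curve maximum and raising Cr0 lifts it", {
  mx <- function(gen, cr0)
    locate_extrema(kinetic_scenario(42, -0.1, 24, 100, gen, cr0))$max_value
  for (cr0 in c(8, 10, 12))
    expect_true(all(diff(sapply(c(50, 70, 90), mx, cr0 = cr0)) < 0))
  for (gen in c(50, 70, 90))
    expect_true(all(diff(sapply(c(8, 10, 12), function(c0) mx(gen, c0))) > 0))
  # far from tangency the max/min pair can annihilate: the curve for
  # Gen = 90, Cr0 = 6 is monotone and its extrema are reported absent
  cp <- locate_extrema(kinetic_scenario(42, -0.1, 24, 100, 90, 6))
  expect_true(is.na(cp$max_dvdt) && is.na(cp$min_dvdt))
})

test_that("positivity interval brackets the positive maximum", {
  s <- worked_scenario()
  iv <- positivity_interval(s)
  expect_length(iv, 2)
  expect_true(iv[1] < -0.3 && iv[2] > 0.08)   # contains -0.3, -0.1, +0.08
  expect_lt(iv[2], 1)                          # but not +1 L/h
  expect_lt(abs(first_derivative(s, iv[1])), 1e-9)
  expect_lt(abs(first_derivative(s, iv[2])), 1e-9)
  expect_gt(first_derivative(s, mean(iv)), 0)
  cp <- locate_extrema(s)
  expect_true(iv[1] < cp$max_dvdt && cp$max_dvdt < iv[2])
  # always-negative curve: empty interval
  expect_length(positivity_interval(aki_scenario()), 0)
})

test_that("trajectory crossing and catch-up times match the CRRT race", {
  s <- worked_scenario()
  tc <- crossing_time(s, -0.3, -0.1)
  expect_lt(abs(tc - 22), 0.5)
  expect_equal(crossing_time(s, -0.1, -0.3), tc, tolerance = 1e-6)
  ta <- catchup_time(s, -0.3, -0.1)
  expect_lt(abs(ta - 5.7), 0.5)
  # the gap widens before and narrows after the catch-up time
  gap <- function(tt) cr_at_time(s, t = tt, dvdt = -0.3) -
    cr_at_time(s, t = tt, dvdt = -0.1)
  expect_gt(gap(ta), gap(ta - 1))
  expect_gt(gap(ta), gap(ta + 1))
  # the crossing re-evaluates to a zero gap
  expect_lt(abs(gap(tc)), 1e-9)
  # degenerate equal rates
  expect_true(is.na(crossing_time(s, -0.1, -0.1)))
  expect_true(is.na(catchup_time(s, -0.1, -0.1)))
})
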