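test_that("clearance thresholds are exact rational arithmetic", {
  th <- domain_thresholds(60, 8, 42, 24)
  expect_equal(th[["t_low"]], 60 / 8 + (42 / 24) * (50 / 3), tolerance = 1e-14)
  expect_equal(th[["t_high"]], 2 * (42 / 24) * (50 / 3), tolerance = 1e-14)
  expect_lt(abs(th[["t_low"]] - 36.67), 0.01)
  expect_lt(abs(th[["t_high"]] - 58.33), 0.01)
  # with no generation the lower threshold is exactly half the upper
  th0 <- domain_thresholds(0, 8, 42, 24)
  expect_equal(th0[["t_low"]], th0[["t_high"]] / 2, tolerance = 1e-14)
  expect_error(domain_thresholds(60, 0, 42, 24), class = "crk_invalid_scenario")
})

test_that("the septic CRRT example is top domain with a positive derivative", {
  cl <- classify_scenario(worked_scenario())
  expect_identical(cl$domain, "top")
  expect_true(cl$can_be_positive)
  expect_false(cl$unrealistic)
  expect_identical(cl$sign_at_actual, 1L)
  expect_lt(abs(cl$dvdt_star - (-1.43818)), 1e-4)
  expect_lt(abs(cl$benchmark_gen - 78.42), 5e-3)
  expect_lt(abs(cl$benchmark_cr0 - 4.08), 5e-3)
  expect_length(cl$positivity, 2)
})

test_that("severe AKI is classified always-negative", {
  cl <- classify_scenario(aki_scenario())
  expect_identical(cl$domain, "bottom")
  expect_false(cl$can_be_positive)
  expect_identical(cl$sign_at_actual, -1L)
})

test_that("intermediate clearance lands in the middle domain", {
  cl <- classify_scenario(kinetic_scenario(42, -0.1, 24, 50, 60, 8))
  expect_identical(cl$domain, "middle")
  expect_true(cl$can_be_positive)
  expect_true(cl$unrealistic)
  expect_true(is.na(cl$dvdt_star))
})

test_that("the verdict flips across the benchmark generation rate", {
  mk <- function(gen) kinetic_scenario(42, -0.1, 24, 100, gen, 8)
  # benchmark Gen for Cr0 = 8, GFR_K = 100 is 69.67084
  expect_true(classify_scenario(mk(69.66))$can_be_positive)
  expect_false(classify_scenario(mk(69.68))$can_be_positive)
})

test_that("verdicts are consistent with grid-evaluated derivative signs", {
  fix <- reference_scenarios()
  scens <- c(list(fix$aki, fix$worked, fix$crrt), fix$gen_sweep)
  for (s in scens) {
    cl <- classify_scenario(s)
    grid <- seq(-s$v0 / s$t * (1 - 1e-3), 5, length.out = 200)
    d1 <- first_derivative(s, grid)
    if (isFALSE(cl$can_be_positive)) {
      expect_true(all(d1 < 0))
    } else if (cl$domain == "top") {
      cp <- locate_extrema(s)
      expect_gt(cp$max_value, 0)
      expect_length(cl$positivity, 2)
      expect_true(cl$positivity[1] < cp$max_dvdt &&
                    cp$max_dvdt < cl$positivity[2])
      inside <- grid > cl$positivity[1] & grid < cl$positivity[2]
      expect_true(all(d1[inside] > 0))
      expect_true(all(d1[!inside] <= 0))
    }
  }
})

test_that("domains are adjacent across the upper threshold", {
  th <- domain_thresholds(60, 8, 42, 24)
  mk <- function(g) kinetic_scenario(42, -0.1, 24, g, 60, 8)
  expect_identical(classify_scenario(mk(th[["t_high"]] - 1e-6))$domain, "middle")
  expect_identical(classify_scenario(mk(th[["t_high"]] + 1e-6))$domain, "top")
  expect_identical(classify_scenario(mk(th[["t_low"]] - 1e-6))$domain, "bottom")
  expect_identical(classify_scenario(mk(th[["t_low"]] + 1e-6))$domain, "middle")
  # an exact boundary value goes to the higher domain and is flagged
  clb <- classify_scenario(mk(th[["t_high"]]))
  expect_identical(clb$domain, "top")
  expect_true(clb$on_boundary)
})

test_that("unsupported non-permissive regime raises a distinct error", {
  # Gen/Cr0 + V0/t > 2 V0/t with a clearance above the lower threshold
  s <- kinetic_scenario(42, -0.1, 24, gfrk = 120, gen = 800, cr0 = 4)
  expect_error(classify_scenario(s), class = "crk_unsupported_regime")
})
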