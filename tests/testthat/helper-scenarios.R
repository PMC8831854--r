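# Random valid scenarios for property-style tests. Draw ranges span the
# clinically plausible envelope; the volume rate keeps a margin from the
# exhaustion wall -v0/t and from the removable singularity at
# dvdt = -GFR_K (in L/h), where finite-difference oracles lose accuracy.
random_scenario <- function() {
  v0 <- runif(1, 20, 60)
  t <- runif(1, 6, 48)
  gfrk <- runif(1, 5, 150)
  gen <- runif(1, 10, 150)
  cr0 <- runif(1, 0.5, 12)
  g_lh <- gfrk * 3 / 50
  repeat {
    dvdt <- runif(1, -0.8 * v0 / t, 1.5)
    if (abs(dvdt + g_lh) > 0.02) break
  }
  kinetic_scenario(v0 = v0, dvdt = dvdt, t = t, gfrk = gfrk,
                   gen = gen, cr0 = cr0)
}

worked_scenario <- function(dvdt = -0.1)
  kinetic_scenario(v0 = 42, dvdt = dvdt, t = 24, gfrk = 80, gen = 40, cr0 = 8)

aki_scenario <- function()
  kinetic_scenario(v0 = 42, dvdt = -0.1, t = 24, gfrk = 20, gen = 100, cr0 = 1)
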