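test_that("noiseless decay rates are recovered exactly", {
  tr <- generate_transients(transient_spec(k_syst = 2, k_caff = 0.68,
                                           noise_sd = 0))
  fs <- fit_monoexp(tr$systolic)
  fc <- fit_monoexp(tr$caffeine)
  expect_equal(fs$k, 2, tolerance = 1e-6)
  expect_equal(fc$k, 0.68, tolerance = 1e-6)
})

test_that("non-decaying traces are flagged failures", {
  t <- seq(0, 5, by = 0.01)
  f <- fit_monoexp(data.frame(time_s = t, value = rep(3, length(t))))
  expect_false(f$ok)
  rising <- fit_monoexp(data.frame(time_s = t, value = t))
  expect_false(rising$ok)
})

test_that("k is invariant to time origin and affine intensity transforms", {
  tr <- generate_transients(transient_spec(k_syst = 1.3, k_caff = 0.6,
                                           noise_sd = 0.02, seed = 8))
  d <- tr$systolic
  k0 <- fit_monoexp(d)$k
  shifted <- data.frame(time_s = d$time_s + 11.7, value = d$value)
  scaled <- data.frame(time_s = d$time_s, value = 5 * d$value - 2)
  expect_equal(fit_monoexp(shifted)$k, k0, tolerance = 1e-6)
  expect_equal(fit_monoexp(scaled)$k, k0, tolerance = 1e-6)
})

test_that("flux partition arithmetic and invariants hold", {
  fp <- partition_fluxes(2.0, 0.8)
  expect_equal(fp$k_serca, 1.2, tolerance = 1e-12)
  expect_equal(fp$frac_serca, 0.6, tolerance = 1e-12)
  expect_equal(fp$frac_non_serca, 0.4, tolerance = 1e-12)
  ## boundary: equal rates mean zero SERCA flux
  fp0 <- partition_fluxes(0.9, 0.9)
  expect_equal(fp0$k_serca, 0, tolerance = 1e-12)
  expect_equal(fp0$frac_serca, 0, tolerance = 1e-12)
  ## property sweep: fractions always sum to one
  for (s in 1:25) {
    ks <- tatnet:::with_seed(s, sort(stats::runif(2, 0.1, 5)))
    fp <- partition_fluxes(ks[2], ks[1])
    expect_equal(fp$frac_serca + fp$frac_non_serca, 1, tolerance = 1e-12)
    expect_gte(fp$k_serca, 0)
  }
  expect_error(partition_fluxes(0.5, 0.9), "assumption")
})

test_that("current densities normalize peak and charge by capacitance", {
  t <- seq(0, 1, by = 1e-4)
  ## capacitance scale of an atrial myocyte; peak set for -10 pA/pF
  i <- rep(0, length(t)); i[t >= 0.2 & t <= 0.4] <- -770.7
  tr <- tat_trace(t, i, kind = "current", capacitance = 77.07)
  cd <- current_density(tr, window = c(0, 1), caffeine = TRUE)
  expect_equal(cd$peak_density, -10, tolerance = 1e-9)
  ## rectangle charge: -770.7 pA * 0.2 s, trapezoid within 0.1%
  expect_equal(cd$integral_density, -770.7 * 0.2 / 77.07,
               tolerance = 0.001 * abs(-770.7 * 0.2 / 77.07))
  expect_equal(cd$sr_content_proxy, cd$integral_density)
  ## zero current
  tr0 <- tat_trace(t, 0 * t, kind = "current", capacitance = 77.07)
  cd0 <- current_density(tr0)
  expect_equal(cd0$peak_density, 0)
  expect_equal(cd0$integral_density, 0)
  expect_error(current_density(tr, window = c(0.5, 2)), "window")
})

test_that("end-to-end flux recovery stays within 3% at SNR 20", {
  fr <- vapply(1:25, function(s) {
    tr <- generate_transients(transient_spec(k_syst = 2, k_caff = 0.68,
                                             amplitude = 1.5,
                                             noise_sd = 1.5 / 20, seed = s))
    fs <- fit_monoexp(tr$systolic); fc <- fit_monoexp(tr$caffeine)
    partition_fluxes(fs, fc)$frac_serca
  }, numeric(1))
  expect_lt(abs(stats::median(fr) - (1 - 0.68 / 2)), 0.03)
})
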