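test_that("parameter construction validates its fields", {
  expect_error(synapse_params(0, 0.2, 0.0017, 0.0517, 0.1, 1.5, 1), "Pmax")
  expect_error(synapse_params(1.2, 0.2, 0.0017, 0.0517, 0.1, 1.5, 1), "Pmax")
  expect_error(synapse_params(0.85, 0.2, 0.01, 0.005, 0.1, 1.5, 1), "kmax")
  p <- synapse_preset("depressing")
  expect_equal(p$delta_k, p$kmax - p$kmin)
  expect_equal(synapse_preset("muscarine")$delta, 0.17)
  expect_equal(synapse_preset("muscarine")$Pmax, 0.27)
})

test_that("Poisson trains have exponential statistics and are reproducible", {
  isis <- poisson_isis(2, 1e5, seed = 11)
  expect_equal(mean(isis), 500, tolerance = 10 / 500)
  expect_equal(sd(isis) / mean(isis), 1, tolerance = 0.02)
  expect_identical(isis, poisson_isis(2, 1e5, seed = 11))
  expect_false(identical(isis[1], poisson_isis(2, 1, seed = 12)))
  expect_error(poisson_isis(-1, 10), "rate_hz")
  expect_error(poisson_isis(2, 0), "'n'")
})

test_that("single map steps match hand-evaluated responses", {
  # first pulse from rest after a long quiescent interval
  expect_equal(fd_step(fd_rest_state(), 1e6, synapse_preset("mixed"))$pr, 0.3)
  expect_equal(fd_step(fd_rest_state(), 1e6, synapse_preset("depressing"))$pr,
               0.85 / (1 + 0.2^4))
  # full-recovery limit for every preset: Pr -> Pmax delta^4/(delta^4 + K^4)
  for (nm in c("depressing", "muscarine", "facilitating", "mixed")) {
    p <- synapse_preset(nm)
    lim <- p$Pmax * p$delta^4 / (p$delta^4 + p$K^4)
    st <- list(C = 0.7, R = 0.4, P = 0.5)
    expect_equal(fd_step(st, 1e6, p)$pr, lim, tolerance = 1e-12)
  }
  expect_error(fd_step(fd_rest_state(), -1, synapse_preset("mixed")),
               "isi_ms")
  expect_error(fd_step(list(C = NaN, R = 1, P = 0), 10,
                       synapse_preset("mixed")), "non-finite")
})

test_that("simulation respects length, bounds and convergence contracts", {
  p <- synapse_preset("depressing")
  tr <- fd_simulate(p, rep(20, 200), discard = 0)
  # monotone non-increasing after the first pulse, converging to the fixed pt
  expect_true(all(diff(tr$Pr) <= 1e-12))
  expect_equal(tail(tr$Pr, 1), fd_fixed_point(p, 20)$PRbar, tolerance = 1e-6)

  isis <- poisson_isis(10, 32868, seed = 3)
  out <- fd_simulate(p, isis, discard = 100)
  expect_identical(nrow(out), 32768L)
  expect_equal(out$Pr, out$P * out$R)

  mus <- synapse_preset("muscarine")
  tm <- fd_simulate(mus, poisson_isis(20, 5000, seed = 4), discard = 0)
  expect_true(all(tm$Pr >= 0 & tm$Pr <= mus$Pmax))

  expect_error(fd_simulate(p, numeric(0)), "empty")
  expect_error(fd_simulate(p, rep(10, 50), discard = 50), "discard")
})

test_that("trajectories satisfy the map invariants for every preset", {
  for (nm in c("depressing", "muscarine", "facilitating", "mixed")) {
    p <- synapse_preset(nm)
    isis <- poisson_isis(40, 4000, seed = 17)
    tr <- fd_simulate(p, isis, discard = 0)
    expect_true(all(tr$Pr >= 0 & tr$Pr <= p$Pmax))
    expect_true(all(tr$R >= 0 & tr$R <= 1))
    cmax <- p$delta / (1 - exp(-min(isis) / p$tau_ca))
    expect_true(all(tr$C <= cmax + 1e-12))
  }
})

test_that("closed-form fixed points agree with long iteration of the map", {
  # calcium geometric-series closed form at T = tau_ca * ln 2
  p <- synapse_preset("mixed")
  expect_equal(fd_fixed_point(p, p$tau_ca * log(2))$Cbar, 2 * p$delta)
  for (nm in c("depressing", "muscarine", "facilitating", "mixed")) {
    pp <- synapse_preset(nm)
    for (T_ms in c(4, 10, 20, 100, 1000)) {
      fp <- fd_fixed_point(pp, T_ms)
      it <- fd_simulate(pp, rep(T_ms, 10000), discard = 9999)
      expect_equal(it$C, fp$Cbar, tolerance = 1e-8)
      expect_equal(it$P, fp$Pbar, tolerance = 1e-8)
      expect_equal(it$R, fp$Rbar, tolerance = 1e-8)
      expect_equal(it$Pr, fp$PRbar, tolerance = 1e-8)
    }
  }
  # long-interval limit: full recovery
  pd <- synapse_preset("depressing")
  expect_equal(fd_fixed_point(pd, 1e6)$PRbar, 0.85 / (1 + 0.2^4),
               tolerance = 1e-10)
})

test_that("fixed-point spectra show the three canonical rate dependences", {
  rates <- c(0.1, 0.5, 1, 2, 5, 10, 20, 35, 50, 65, 80, 100)
  dep <- fixed_point_spectrum(synapse_preset("depressing"), rates)
  expect_true(all(diff(dep$PRbar) < 0))

  rates_wide <- c(0.1, 1, 5, 10, 25, 40, 50, 60, 75, 100, 150, 200, 250)
  mix <- fixed_point_spectrum(synapse_preset("mixed"), rates_wide)
  d <- diff(mix$PRbar)
  sgn <- sign(d[abs(d) > 1e-6])      # the response is flat to ~1e-8 below 1 Hz
  expect_equal(sum(diff(sgn) != 0), 1)   # one interior maximum
  peak <- mix$rate_hz[which.max(mix$PRbar)]
  expect_gt(peak, 25); expect_lt(peak, 75)

  fac <- fixed_point_spectrum(synapse_preset("facilitating"), c(1, 100))
  expect_gt(fac$PRbar[2], fac$PRbar[1])

  expect_error(fixed_point_spectrum(synapse_preset("mixed"), c(1, 1)),
               "distinct")
})

test_that("pulse trains round-trip through CSV export", {
  tr <- fd_simulate(synapse_preset("mixed"), poisson_isis(20, 300, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pulse_train(tr, path)
  back <- read.csv(path)
  expect_named(back, c("pulse_index", "isi_ms", "C", "P", "R", "Pr"))
  expect_equal(back$Pr, tr$Pr)
})
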