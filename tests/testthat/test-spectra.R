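# Spectral analysis: Pade transforms, strength functions, HHG, cutoff law.

test_that("Pade transform of trivial and single-line signals", {
  om <- seq(0.01, 1, by = 1e-3)
  z <- pade_fourier(numeric(500), 0.1, om)
  expect_true(all(z == 0))
  ## damped cosine: |transform| maximal at the grid point nearest omega0
  w0 <- 0.35; dt <- 0.1; tt <- (0:1999) * dt
  sig <- cos(w0 * tt) * exp(-1e-3 * tt)
  ft <- pade_fourier(sig, dt, om, gamma = 1e-4)
  expect_equal(om[which.max(Mod(ft))], w0, tolerance = 2e-3)
})

test_that("Pade agrees with the direct discrete sum where both converge", {
  ## random multi-line signal, damped hard enough that the windowed direct
  ## sum is converged (e^(-gamma T) ~ 1e-4)
  set.seed(21)
  n <- 300; dt <- 0.2
  tt <- (0:(n - 1)) * dt
  amps <- stats::runif(6, 0.2, 1)
  freqs <- stats::runif(6, 0.2, 2.5)
  sig <- colSums(amps * sin(outer(freqs, tt)))
  gamma <- 0.15
  om <- seq(0.05, 0.5, by = 0.05)
  pade <- pade_fourier(sig, dt, om, gamma = gamma)
  direct <- vapply(om, function(w) dt * sum(sig * exp(-gamma * tt) * exp(1i * w * tt)),
                   complex(1))
  expect_lt(max(Mod(pade - direct) / Mod(direct)), 0.01)
})

test_that("strength functions vanish for null traces and find a pure line", {
  mk_trace <- function(muz) {
    structure(list(times = (0:999) * 0.1,
                   mu = rbind(0, 0, muz), field = matrix(0, 3, 1000),
                   trace_of_D = rep(5, 1000),
                   kick = field_spec("delta_kick", direction = c(0, 0, 1)),
                   mu0 = c(0, 0, muz[1])), class = "rt_dipole_trace")
  }
  z <- mk_trace(numeric(1000))
  sp <- strength_function(list(z, z, z), kappa = 1e-5)
  expect_true(all(sp$S == 0))
  ## synthetic oscillation at 0.4 a.u.
  tt <- (0:999) * 0.1
  sp1 <- strength_function(mk_trace(1e-5 * sin(0.4 * tt)), kappa = 1e-5)
  pk <- find_spectrum_peaks(sp1, 3, min_height_frac = 0.2)
  expect_equal(pk$omega[1], 0.4, tolerance = 2e-3)
  ## mismatched grids are rejected
  short <- mk_trace(numeric(1000)); short$times <- short$times + 1e-3
  expect_error(strength_function(list(z, z, short), kappa = 1e-5), "mismatched")
})

test_that("HHG spectra resolve pure and odd-only tones", {
  w0 <- 0.06
  ncyc <- 30
  tau <- ncyc * 2 * pi / w0
  tt <- seq(0, tau, by = 0.5)
  mk <- function(muz) structure(list(times = tt, mu = rbind(0, 0, muz),
                                     field = matrix(0, 3, length(tt)),
                                     trace_of_D = rep(1, length(tt)),
                                     mu0 = c(0, 0, muz[1])),
                                class = "rt_dipole_trace")
  h3 <- hhg_spectrum(mk(sin(3 * w0 * tt)), w0, tau)
  expect_equal(h3$harmonic_orders[which.max(h3$power)], 3, tolerance = 0.05)
  ## odd tones 1,3,5: even orders >= 3 decades down (their only content is
  ## rectangular-window leakage from the odd lines)
  modd <- sin(w0 * tt) + 0.7 * sin(3 * w0 * tt) + 0.5 * sin(5 * w0 * tt)
  h <- hhg_spectrum(mk(modd), w0, tau)
  at_order <- function(k) max(h$log10_P[abs(h$harmonic_orders - k) < 0.2])
  odd <- vapply(c(1, 3, 5), at_order, numeric(1))
  even <- vapply(c(2, 4), at_order, numeric(1))
  expect_true(all(min(odd) - even >= 3))
  expect_error(hhg_spectrum(mk(modd), w0, tau = -1), "tau")
  expect_error(hhg_spectrum(mk(modd), w0, tau = max(tt) * 2), "exceeds")
})

test_that("a strongly driven two-level system emits odd harmonics", {
  ## brute-force ODE-style check: the same model propagated with a fine-step
  ## Magnus loop is the oracle for the production machinery
  w0 <- 0.08
  model <- make_two_level_fixture(V = 0, gap = 3 * w0)   # resonant-ish 2-level
  field <- field_spec("cos2_pulse", direction = c(0, 0, 1), E0 = 0.04,
                      omega0 = w0, n_cycles = 20)
  out <- propagate_model(model, dt = 0.05, n_steps = ceiling(field$tau / 0.05),
                         field = field)
  tr <- structure(list(times = out$times, mu = rbind(0, 0, out$dipole),
                       field = matrix(0, 3, length(out$times)),
                       trace_of_D = rep(1, length(out$times)),
                       mu0 = c(0, 0, out$dipole[1])), class = "rt_dipole_trace")
  h <- hhg_spectrum(tr, w0, field$tau, max_harmonic = 8)
  at_order <- function(k) max(h$log10_P[abs(h$harmonic_orders - k) < 0.15])
  ## emission below the two-level gap (3 w0): orders 1 and 3 dominate the
  ## even orders between them by decades
  odd <- vapply(c(1, 3), at_order, numeric(1))
  even <- vapply(c(2, 4), at_order, numeric(1))
  expect_gt(min(odd) - max(even), 1)

  ## fine-step brute-force propagation of the same model is the oracle
  out2 <- propagate_model(model, dt = 0.01, n_steps = ceiling(field$tau / 0.01),
                          field = field)
  idx <- seq(1, length(out2$times), by = 5)
  expect_lt(max(abs(out$dipole - out2$dipole[idx])), 1e-4)
})

test_that("the semiclassical cutoff law is exact closed-form arithmetic", {
  ce <- cutoff_estimate(E = 0.054, omega0 = 0.05696, I_p = 0.4637)
  expect_equal(ce$U_p, 0.054^2 / (4 * 0.05696^2), tolerance = 1e-15)
  expect_equal(ce$E_cutoff, ce$U_p * 3.17 + 0.4637, tolerance = 1e-15)
  expect_equal(round(ce$N_max), 21)
  zero <- cutoff_estimate(E = 0, omega0 = 0.05696, I_p = 0.4637)
  expect_equal(zero$E_cutoff, 0.4637)
  expect_error(cutoff_estimate(0.054, 0, 0.4637), "omega0")
})

test_that("spectrum files round-trip key columns", {
  om <- seq(0.1, 0.5, by = 0.01)
  sp <- structure(list(omega = om, energy_ev = om * 27.211386245988,
                       S = sin(om), alpha_diag = list(), gamma = 1e-4,
                       method = "pade"), class = "rt_spectrum")
  path <- tempfile(fileext = ".dat")
  write_spectrum(sp, path)
  m <- as.matrix(read.table(path, comment.char = "#"))
  expect_equal(m[, 1], om, tolerance = 1e-9)
  expect_equal(m[, 3], sin(om), tolerance = 1e-9)
  unlink(path)
})
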