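# Fields, kicks, Magnus steps, predictor/corrector, full propagation.

test_that("cos2 pulse envelope obeys its closed form and support", {
  w0 <- 0.05696; E0 <- 0.054; nc <- 20
  f <- field_spec("cos2_pulse", direction = c(0, 0, 1), E0 = E0, omega0 = w0,
                  n_cycles = nc)
  expect_equal(f$tau, nc * 2 * pi / w0, tolerance = 1e-12)
  expect_equal(field_value(f, 0)[3, 1], 0)                     # sin factor
  expect_equal(field_value(f, f$tau * 1.001)[3, 1], 0)         # outside support
  expect_equal(field_value(f, -1)[3, 1], 0)
  ## envelope maximum at tau/2: E0 |sin(w0 tau / 2)| by direct evaluation
  expect_equal(field_value(f, f$tau / 2)[3, 1], E0 * sin(w0 * f$tau / 2),
               tolerance = 1e-12)
  ## delta kick carries no explicit field
  k <- field_spec("delta_kick", kappa = 1e-5)
  expect_true(all(field_value(k, seq(0, 10, 0.5)) == 0))
})

test_that("delta kicks are unitary and linear in the weak-field regime", {
  gs <- water_gs()
  D0 <- initial_density(gs)
  ints <- gs$system$ints
  expect_equal(apply_delta_kick(D0, 0, c(0, 0, 1), ints, gs$mo_coeffs), D0 + 0i)
  Dk <- apply_delta_kick(D0, 0.2, c(0, 0, 1), ints, gs$mo_coeffs)
  expect_equal(Re(sum(diag(Dk))), 5, tolerance = 1e-12)
  expect_lt(max(abs(Dk %*% Dk - Dk)), 1e-12)
  ## induced dipole at t = 0+ linear in kappa across 1e-5 and 2e-5
  Pmo <- crossprod(gs$mo_coeffs, ints$dipole$z %*% gs$mo_coeffs)
  mu_of <- function(kap) {
    D <- apply_delta_kick(D0, kap, c(0, 0, 1), ints, gs$mo_coeffs)
    ## dipole immediately after one short step (the kick itself leaves the
    ## density, hence mu, unchanged at t = 0; probe the first response)
    sys <- gs$system
    fock <- function(Dm, t) {
      Dr <- 2 * (gs$mo_coeffs %*% Re(Dm) %*% t(gs$mo_coeffs))
      crossprod(gs$mo_coeffs, build_fock_ao(sys, Dr) %*% gs$mo_coeffs)
    }
    st <- predictor_corrector_step(D, 0, 0.2, fock, pc_tol = 1e-10)
    -2 * Re(sum(t(Pmo) * st$D))
  }
  mu0 <- mu_of(0)
  d1 <- mu_of(1e-5) - mu0
  d2 <- mu_of(2e-5) - mu0
  expect_equal(d2 / d1, 2, tolerance = 1e-3)
})

test_that("Magnus steps are exact for closed forms and preserve spectra", {
  ## diagonal F, projector D: phases cancel
  D <- initial_density(n_occ = 1, n_basis = 3)
  Fd <- diag(c(-0.5, 0.1, 0.7))
  expect_equal(magnus_step(D, Fd, 0.3), D, tolerance = 1e-14)
  ## 2x2 Rabi: population transfer sin^2(V t)
  V <- 0.1
  F2 <- matrix(c(0, V, V, 0), 2, 2)
  D2 <- initial_density(n_occ = 1, n_basis = 2)
  tstep <- 0.7
  Dt <- magnus_step(D2, F2, tstep)
  expect_equal(Re(Dt[2, 2]), sin(V * tstep)^2, tolerance = 1e-12)
  ## eigenvalues of D preserved under a random Hermitian F
  set.seed(3)
  A <- matrix(stats::rnorm(16), 4, 4) + 1i * matrix(stats::rnorm(16), 4, 4)
  H <- (A + Conj(t(A))) / 2
  D4 <- initial_density(n_occ = 2, n_basis = 4)
  D4t <- magnus_step(D4, H, 1.3)
  expect_equal(sort(Re(eigen(D4t, only.values = TRUE)$values)),
               c(0, 0, 1, 1), tolerance = 1e-12)
  ## a non-Hermitian Fock is rejected
  bad <- H; bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(magnus_step(D4, bad, 0.1), "non-Hermitian")
})

test_that("predictor/corrector converges instantly for static Hamiltonians", {
  model <- make_two_level_fixture(V = 0.05, gap = 0.3)
  fock <- function(D, t) model$hamiltonian
  D <- initial_density(n_occ = 1, n_basis = 2)
  st <- predictor_corrector_step(D, 0, 0.1, fock, pc_tol = 1e-9)
  expect_lte(st$n_iter, 2)
  expect_error(predictor_corrector_step(D, 0, 0.1, fock, pc_tol = 0,
                                        pc_max_iter = 3),
               "did not converge")
})

test_that("two-level dynamics match the generalized Rabi closed form", {
  for (par in list(c(0.1, 0), c(0.07, 0.25))) {
    model <- make_two_level_fixture(V = par[1], gap = par[2])
    out <- propagate_model(model, dt = 0.01, n_steps = 2000)
    expect_equal(out$populations[2, ], model$population2(out$times),
                 tolerance = 1e-8)
  }
  ## V = 0: populations constant
  still <- propagate_model(make_two_level_fixture(V = 0, gap = 0.3),
                           dt = 0.05, n_steps = 200)
  expect_equal(still$populations[1, ], rep(1, 201), tolerance = 1e-12)
  ## gap = 0: full transfer with period pi / V
  per <- propagate_model(make_two_level_fixture(V = 0.1), dt = 0.01,
                         n_steps = round(pi / 0.1 / 0.01))
  expect_equal(per$populations[1, length(per$times)], 1, tolerance = 1e-6)
})

test_that("propagation is time-reversal symmetric", {
  gs <- water_gs()
  f <- field_spec("delta_kick", direction = c(0, 0, 1), kappa = 1e-3)
  fwd <- propagate(gs, f, propagation_config(dt = 0.1, n_steps = 100))
  ## propagate backward from the final state with dt -> -dt
  sys <- gs$system
  C <- gs$mo_coeffs
  fock <- function(Dm, t) {
    Dr <- 2 * (C %*% Re(Dm) %*% t(C))
    crossprod(C, build_fock_ao(sys, Dr) %*% C)
  }
  D <- fwd$D_final
  for (s in 100:1) {
    st <- predictor_corrector_step(D, s * 0.1, -0.1, fock, pc_tol = 1e-9)
    D <- st$D
  }
  D0 <- apply_delta_kick(initial_density(gs), 1e-3, c(0, 0, 1), sys$ints, C)
  expect_lt(max(abs(D - D0)), 1e-6)
})

test_that("mo/ao transforms are metric-consistent round trips", {
  gs <- water_gs()
  S <- gs$system$ints$overlap
  C <- gs$mo_coeffs
  ## overlap transforms to the identity
  expect_equal(mo_ao_transform(S, C, S, "fock_ao_to_mo"), diag(7), tolerance = 1e-10)
  set.seed(5)
  Dmo <- crossprod(matrix(stats::rnorm(49), 7, 7))
  Dao <- mo_ao_transform(Dmo, C, S, "density_mo_to_ao")
  back <- mo_ao_transform(Dao, C, S, "density_ao_to_mo")
  expect_equal(back, Dmo, tolerance = 1e-10)
  expect_equal(sum(diag(Dao %*% S)), sum(diag(Dmo)), tolerance = 1e-10)
  ## Fock round trip
  Fmo <- mo_ao_transform(build_fock_ao(gs$system, gs$D_ao), C, S, "fock_ao_to_mo")
  Fao <- mo_ao_transform(Fmo, C, S, "fock_mo_to_ao")
  expect_equal(mo_ao_transform(Fao, C, S, "fock_ao_to_mo"), Fmo, tolerance = 1e-9)
  expect_error(mo_ao_transform(S, C * 1.01, S, "fock_ao_to_mo"), "orthonormal")
})

test_that("a stationary state stays stationary without a field", {
  gs <- water_gs()
  tr <- propagate(gs, field_spec("delta_kick", kappa = 0),
                  propagation_config(dt = 0.1, n_steps = 500))
  expect_lt(max(abs(tr$mu - tr$mu0)), 1e-8)
  expect_lt(max(abs(tr$trace_of_D - 5)), 1e-9)
})

test_that("dipole traces round-trip through the plain-text format", {
  gs <- water_gs()
  tr <- propagate(gs, field_spec("delta_kick", direction = c(0, 0, 1), kappa = 1e-4),
                  propagation_config(dt = 0.1, n_steps = 20))
  path <- tempfile(fileext = ".dat")
  write_dipole_trace(tr, path)
  back <- read_dipole_trace(path)
  expect_equal(back$times, tr$times, tolerance = 1e-12)
  expect_equal(back$mu, tr$mu, tolerance = 1e-10)
  unlink(path)
})
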