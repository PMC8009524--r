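# Embedding machinery: nonadditive potentials/energies, environment
# electrostatics, assembly and AO projection.

test_that("nonadditive quantities vanish for a vanishing environment", {
  set.seed(7)
  r1 <- 10^stats::runif(200, -8, 0.5)
  zero <- numeric(200)
  v <- nonadditive_potential(r1, zero)
  expect_true(all(v$v_nad_kin == 0))
  expect_true(all(v$v_nad_xc == 0))
  e <- nonadditive_energy(r1, zero, weights = rep(1e-3, 200))
  expect_equal(e$E_nad_kin, 0)
  expect_equal(e$E_nad_xc, 0)
})

test_that("nonadditive TF potential is nonnegative and energies symmetric", {
  set.seed(8)
  r1 <- 10^stats::runif(200, -8, 0.5)
  r2 <- 10^stats::runif(200, -8, 0.5)
  v <- nonadditive_potential(r1, r2)
  expect_true(all(v$v_nad_kin >= 0))
  w <- rep(2e-3, 200)
  e12 <- nonadditive_energy(r1, r2, w)
  e21 <- nonadditive_energy(r2, r1, w)
  expect_equal(e12$E_nad_kin, e21$E_nad_kin, tolerance = 1e-12)
  expect_equal(e12$E_nad_xc, e21$E_nad_xc, tolerance = 1e-12)
})

test_that("flat-density nonadditive kinetic energy matches the closed form", {
  ## rho_I = rho_II = rho0 on a box of volume V (unit weights emulate it):
  ## E_nad_kin = C_TF V rho0^(5/3) (2^(5/3) - 2)
  rho0 <- 0.3; npts <- 50; w <- rep(0.1, npts)
  V <- sum(w)
  e <- nonadditive_energy(rep(rho0, npts), rep(rho0, npts), w)
  C_TF <- 0.3 * (3 * pi^2)^(2 / 3)
  expect_equal(e$E_nad_kin, C_TF * V * rho0^(5 / 3) * (2^(5 / 3) - 2),
               tolerance = 1e-10)
})

test_that("potential and energy are consistent as functional derivatives", {
  ## |FD of E_nad under rho_I -> rho_I + lambda drho  -  int v_nad drho|
  ## small for a perturbation with ||drho||_1 = 1e-3
  sys <- water_system()
  gs <- water_gs()
  rho_I <- density_on_grid(gs$D_ao, sys$aovals, sys$grid)$values
  w <- sys$grid$weights
  ## smooth environment-like density: displaced s-type blob
  d2 <- rowSums(sweep(sys$grid$points, 2, c(0, 0, 4))^2)
  rho_II <- 2 * (0.7 / pi)^1.5 * exp(-0.7 * d2)
  drho <- (0.5 / pi)^1.5 * exp(-0.5 * rowSums(sys$grid$points^2))
  drho <- drho * (1e-3 / sum(w * drho))           # ||drho||_1 = 1e-3
  lam <- 1
  ep <- nonadditive_energy(rho_I + lam * drho, rho_II, w)
  em <- nonadditive_energy(rho_I - lam * drho, rho_II, w)
  fd_kin <- (ep$E_nad_kin - em$E_nad_kin) / (2 * lam)
  fd_xc <- (ep$E_nad_xc - em$E_nad_xc) / (2 * lam)
  v <- nonadditive_potential(rho_I, rho_II)
  expect_lt(abs(fd_kin - sum(w * v$v_nad_kin * drho)), 1e-5)
  expect_lt(abs(fd_xc - sum(w * v$v_nad_xc * drho)), 1e-5)
})

test_that("environment electrostatics: point charge and Gaussian closed forms", {
  ## bare proton at origin, zero density, probe at (2,0,0)
  proton <- subsystem("H", c(0, 0, 0), charge = 1)
  fake_grid <- structure(list(points = matrix(c(2, 0, 0), 1, 3),
                              weights = 1, n_points = 1L,
                              scope = "active_only"), class = "rt_grid")
  elec <- environment_electrostatics(proton, function(p) numeric(nrow(p)), fake_grid)
  expect_equal(elec$v_nuc_env, -0.5, tolerance = 1e-12)

  ## spherical Gaussian density via an exact basis representation: a single
  ## normalized s function with exponent alpha/2 squares to the model density
  alpha <- 0.8
  sh <- list(l = 0L, centers = matrix(0, 1, 3), nprim = 1L,
             alpha = alpha / 2,
             coef = (2 * (alpha / 2) / pi)^0.75, n_basis = 1L)
  r <- c(0.3, 1, 2.5, 6, 12)
  pts <- cbind(r, 0, 0)
  v <- rtfde:::esp_of_density(sh, matrix(1), pts)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  expect_equal(v, erf(sqrt(alpha) * r) / r, tolerance = 1e-8)

  ## and the analytic fixture agrees with the same closed form
  fx <- make_gaussian_env_fixture(alpha = alpha, n_electrons = 1)
  expect_equal(fx$potential(pts), erf(sqrt(alpha) * r) / r, tolerance = 1e-12)
  expect_equal(fx$potential(matrix(0, 1, 3)), 2 * sqrt(alpha / pi), tolerance = 1e-9)
  rfar <- 10 / sqrt(alpha)
  expect_equal(fx$potential(matrix(c(rfar, 0, 0), 1, 3)), 1 / rfar, tolerance = 1e-12)
})

test_that("a neutral far-away environment is electrostatically screened", {
  ad <- builtin_geometry("h2o_nh3_adduct")
  env <- ad$environment
  env$coords <- env$coords + matrix(rep(c(0, 0, 10 / 0.52917721092), each = 4), ncol = 3)
  env_scf <- scf_ground_state(ks_system(env))
  g <- build_grid(ad$active, preset = "coarse")
  elec <- environment_electrostatics(env, env_scf$D_ao, g)
  near <- rowSums(sweep(g$points, 2, c(0, 0, 2.95 / 0.52917721092))^2) < 16
  expect_lt(max(abs(elec$v_nuc_env[near] + elec$v_coul_env[near])), 0.02)
})

test_that("AO projection is linear and reproduces the overlap for v = 1", {
  sys <- water_system()
  w <- sys$grid$weights
  ao <- sys$aovals
  n <- sys$grid$n_points
  expect_equal(project_potential_to_ao(numeric(n), ao, w), matrix(0, 7, 7))
  V1 <- project_potential_to_ao(rep(1, n), ao, w)
  expect_lt(max(abs(V1 - sys$ints$overlap)), 1e-6)
  expect_equal(project_potential_to_ao(rep(2.5, n), ao, w), 2.5 * V1,
               tolerance = 1e-12)
  set.seed(11)
  v1 <- stats::rnorm(n); v2 <- stats::rnorm(n)
  lin <- project_potential_to_ao(0.3 * v1 + 1.7 * v2, ao, w)
  expect_equal(lin, 0.3 * project_potential_to_ao(v1, ao, w) +
                 1.7 * project_potential_to_ao(v2, ao, w), tolerance = 1e-12)
  expect_error(project_potential_to_ao(rep(NaN, n), ao, w), "non-finite")
})

test_that("assembled embedding potentials keep the component identity", {
  sys <- water_system()
  n <- sys$grid$n_points
  z <- numeric(n)
  vz <- assemble_embedding_potential(z, z, z, z, sys$aovals, sys$grid$weights)
  expect_equal(vz$ao_matrix, matrix(0, 7, 7))
  set.seed(12)
  parts <- replicate(4, stats::rnorm(n), simplify = FALSE)
  ve <- assemble_embedding_potential(parts[[1]], parts[[2]], parts[[3]], parts[[4]],
                                     sys$aovals, sys$grid$weights, step = 3L)
  expect_identical(ve$total, parts[[1]] + parts[[2]] + parts[[3]] + parts[[4]])
  expect_equal(ve$ao_matrix, t(ve$ao_matrix))
  expect_identical(ve$timestamp_step, 3L)
  expect_error(assemble_embedding_potential(z, z[-1], z, z, sys$aovals,
                                            sys$grid$weights), "mismatched")
})

test_that("grid dumps round-trip through the plain-text format", {
  sys <- water_system()
  n <- sys$grid$n_points
  set.seed(13)
  parts <- replicate(4, stats::rnorm(n), simplify = FALSE)
  ve <- assemble_embedding_potential(parts[[1]], parts[[2]], parts[[3]], parts[[4]],
                                     sys$aovals, sys$grid$weights)
  path <- tempfile(fileext = ".dat")
  write_grid_dump(ve, sys$grid, path)
  back <- read_grid_dump(path)
  expect_equal(back$total, ve$total, tolerance = 1e-9)
  expect_equal(back$weights, sys$grid$weights, tolerance = 1e-9)
  unlink(path)
})
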