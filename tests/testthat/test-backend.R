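# Gaussian-basis backend: integrals, SCF with injected one-electron
# operators, AO evaluation, linear-response reference.

test_that("subsystem validation enforces the closed-shell contract", {
  expect_error(subsystem("Xx", c(0, 0, 0)), "unknown element")
  expect_error(subsystem("H", c(0, 0, 0)), "odd electron")
  expect_error(subsystem(character(0), NULL), "at least one atom")
  expect_error(subsystem("H", c(0, 0, 0), xc = "b3lyp", charge = 1), "unknown xc")
  s <- subsystem("H", c(0, 0, 0), charge = -1)  # hydride: closed shell
  expect_equal(s$n_electrons, 2L)
})

test_that("single-function systems give a unit overlap", {
  s <- subsystem("H", c(0, 0, 0), charge = -1)
  ints <- ao_integrals(s)
  expect_equal(ints$n_basis, 1L)
  expect_equal(ints$overlap, matrix(1), tolerance = 1e-12)
})

test_that("overlap matrices are Gram matrices (positive definite)", {
  for (name in c("h2o", "nh3")) {
    S <- ao_integrals(builtin_geometry(name))$overlap
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(S, t(S), tolerance = 1e-14)
  }
})

test_that("H2 off-diagonal overlap matches a brute-force quadrature oracle", {
  zsep <- 1.4  # bohr
  h2 <- subsystem(c("H", "H"),
                  rbind(c(0, 0, -zsep / 2), c(0, 0, zsep / 2)) * 0.52917721092,
                  basis = "sto-3g")
  S <- ao_integrals(h2)$overlap
  sh <- rtfde:::build_shells(h2)
  oracle <- overlap_quadrature_oracle(sh$alpha[1:3], sh$coef[1:3], zsep)
  expect_equal(S[1, 2], oracle, tolerance = 1e-8)
})

test_that("Fock builds are Hermitian and stationary at the SCF solution", {
  sys <- water_system()
  gs <- water_gs()
  F <- build_fock_ao(sys, gs$D_ao)
  expect_lt(max(abs(F - t(F))), 1e-12)
  ## F C = S C eps at the converged state
  resid <- F %*% gs$mo_coeffs -
    sys$ints$overlap %*% gs$mo_coeffs %*% diag(gs$mo_energies)
  expect_lt(max(abs(resid)), 1e-5)
  ## v_extra = 0 is the same as absent
  F0 <- build_fock_ao(sys, gs$D_ao, v_extra = matrix(0, 7, 7))
  expect_equal(F, F0, tolerance = 1e-15)
  ## complex density from a propagation-like state: still Hermitian
  Dc <- gs$D_ao + 0i
  Dc[2, 1] <- Dc[2, 1] + 0.01i; Dc[1, 2] <- Dc[1, 2] - 0.01i
  Fc <- build_fock_ao(sys, Dc)
  expect_lt(max(abs(Fc - Conj(t(Fc)))), 1e-12)
})

test_that("scf respects gauge shifts and reproduces the plain ground state", {
  sys <- water_system()
  gs <- water_gs()
  gs0 <- scf_ground_state(sys, v_extra = matrix(0, 7, 7))
  expect_equal(gs0$scf_energy, gs$scf_energy, tolerance = 1e-9)
  ## uniform shift eps*S: orbitals unchanged, eigenvalues shifted by eps
  eps <- 0.05
  gss <- scf_ground_state(sys, v_extra = eps * sys$ints$overlap)
  expect_equal(gss$mo_energies, gs$mo_energies + eps, tolerance = 1e-6)
  expect_equal(abs(gss$mo_coeffs[, 1:5]), abs(gs$mo_coeffs[, 1:5]), tolerance = 1e-5)
})

test_that("static polarizability from a dipole coupling matches finite differences", {
  sys <- water_system()
  kap <- 5e-4
  mu_of <- function(k) {
    g <- scf_ground_state(sys, v_extra = k * sys$ints$dipole$z)
    -sum(g$D_ao * sys$ints$dipole$z)
  }
  mup <- mu_of(kap); mum <- mu_of(-kap)
  alpha_fd <- (mup - mum) / (2 * kap)
  ## single-sided estimate against the central difference
  mu0 <- -sum(water_gs()$D_ao * sys$ints$dipole$z)
  alpha_1s <- (mup - mu0) / kap
  expect_equal(alpha_1s, alpha_fd, tolerance = 2e-2)
  ## a sane static polarizability: positive, O(1-10) a.u.
  expect_gt(alpha_fd, 0.1); expect_lt(alpha_fd, 20)
})

test_that("AO values on the grid match closed forms and decay", {
  h <- subsystem("H", c(0, 0, 0), charge = -1)
  sh <- rtfde:::build_shells(h)
  at_nucleus <- eval_aos_on_grid(h, matrix(0, 1, 3))
  expect_equal(at_nucleus[1, 1], sum(sh$coef), tolerance = 1e-12)
  far <- eval_aos_on_grid(h, matrix(c(50, 0, 0), 1, 3))
  expect_lt(max(abs(far)), 1e-12)
})

test_that("quadrature with AO values reproduces the analytic overlap", {
  sys <- water_system()
  Sq <- crossprod(sys$aovals, sys$grid$weights * sys$aovals)
  expect_lt(max(abs(Sq - sys$ints$overlap)), 1e-6)
})

test_that("linear-response roots are positive, sorted, and v_extra-consistent", {
  lr <- water_lr()
  expect_true(all(lr$roots$energy_hartree > 0))
  expect_true(!is.unsorted(lr$roots$energy_hartree))
  gs0 <- scf_ground_state(water_system(), v_extra = matrix(0, 7, 7))
  lr0 <- lr_tddft(gs0, n_roots = 6)
  expect_equal(lr0$roots$energy_hartree, water_lr()$roots$energy_hartree,
               tolerance = 1e-7)
})
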