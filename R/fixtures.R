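## Analytic model systems used as propagator oracles and environment
## stand-ins: a driven two-level system with closed-form Rabi dynamics, and a
## spherical Gaussian model density with closed-form electrostatics.

#' Two-level model system
#'
#' H = [[0, V], [V, gap]] with dipole operator sigma_x. Starting from the
#' lower basis state, the population of state 2 follows the generalized Rabi
#' formula P2(t) = V^2 / Omega^2 sin^2(Omega t) with
#' Omega = sqrt(V^2 + gap^2 / 4); for gap = 0 the transfer period is pi / V.
#'
#' @param V coupling (a.u.).
#' @param gap energy splitting (a.u.).
#' @return object of class `rt_two_level`: `hamiltonian`, `dipole_op`,
#'   `n_occ`, and `population2(t)` (the closed-form oracle).
#' @export
make_two_level_fixture <- function(V, gap = 0) {
  if (V < 0 || gap < 0) stop("V and gap must be >= 0")
  Omega <- sqrt(V^2 + gap^2 / 4)
  structure(list(
    hamiltonian = matrix(c(0, V, V, gap), 2, 2),
    dipole_op = matrix(c(0, 1, 1, 0), 2, 2),
    n_occ = 1L,
    population2 = function(t) {
      if (Omega == 0) return(numeric(length(t)))
      (V^2 / Omega^2) * sin(Omega * t)^2
    }
  ), class = "rt_two_level")
}

#' Propagate a small model system
#'
#' Runs the same predictor/corrector midpoint-Magnus machinery as the
#' molecular propagation on an arbitrary (possibly driven) model
#' Hamiltonian, in the model's own orthonormal basis.
#'
#' @param model an `rt_two_level` (or list with `hamiltonian`, `dipole_op`,
#'   `n_occ`).
#' @param dt,n_steps propagation parameters.
#' @param field optional [field_spec()]; its projection on the model's single
#'   dipole operator drives the system.
#' @param pc_tol,pc_max_iter predictor/corrector control.
#' @param D0 initial density (defaults to the occupied-block projector).
#' @return list: `times`, `populations` (n_basis x n_records), `D_final`,
#'   `dipole` (expectation of `dipole_op`), `pc_iters`.
#' @export
propagate_model <- function(model, dt, n_steps, field = NULL, pc_tol = 1e-10,
                            pc_max_iter = 30, D0 = NULL) {
  H0 <- model$hamiltonian
  n <- nrow(H0)
  if (is.null(D0)) {
    D0 <- matrix(0 + 0i, n, n)
    diag(D0)[seq_len(model$n_occ)] <- 1
  }
  fock <- function(D, t) {
    F <- H0
    if (!is.null(field)) {
      Ef <- field_value(field, t)[, 1]
      ## model systems carry one dipole operator; drive with |E|(t) signed
      ## along the field's own direction
      F <- F + sum(Ef * field$direction) * model$dipole_op
    }
    F
  }
  D <- D0
  times <- (0:n_steps) * dt
  pops <- matrix(0, n, n_steps + 1)
  dip <- numeric(n_steps + 1)
  pops[, 1] <- Re(diag(D))
  dip[1] <- Re(sum(t(model$dipole_op) * D))
  iters <- integer(n_steps)
  F_hist <- list()
  for (s in seq_len(n_steps)) {
    F_guess <- if (length(F_hist) == 2) 2 * F_hist[[2]] - F_hist[[1]]
    else if (length(F_hist) == 1) F_hist[[1]] else NULL
    st <- predictor_corrector_step(D, (s - 1) * dt, dt, fock, F_guess = F_guess,
                                   pc_tol = pc_tol, pc_max_iter = pc_max_iter)
    D <- st$D
    iters[s] <- st$n_iter
    F_hist <- if (length(F_hist) == 0) list(st$F_mid) else list(F_hist[[length(F_hist)]], st$F_mid)
    pops[, s + 1] <- Re(diag(D))
    dip[s + 1] <- Re(sum(t(model$dipole_op) * D))
  }
  list(times = times, populations = pops, D_final = D, dipole = dip,
       pc_iters = iters)
}

#' Spherical Gaussian model environment
#'
#' A normalized Gaussian density n_e (alpha/pi)^(3/2) exp(-alpha r^2)
#' centered at `center`, with its closed-form electrostatic potential
#' n_e erf(sqrt(alpha) r) / r (limit 2 n_e sqrt(alpha/pi) at r = 0). Used as
#' an analytic oracle for the environment-electrostatics machinery.
#'
#' @param center 3-vector (bohr).
#' @param alpha Gaussian exponent (bohr^-2).
#' @param n_electrons number of electrons carried by the density.
#' @return list: `density(points)`, `potential(points)` (both vectorized
#'   over N x 3 matrices), `center`, `alpha`, `n_electrons`.
#' @export
make_gaussian_env_fixture <- function(center = c(0, 0, 0), alpha = 1,
                                      n_electrons = 1) {
  if (alpha <= 0) stop("alpha must be > 0")
  center <- as.numeric(center)
  rdist <- function(points) {
    sqrt(rowSums(sweep(matrix(points, ncol = 3), 2, center)^2))
  }
  list(
    density = function(points) {
      r <- rdist(points)
      n_electrons * (alpha / pi)^1.5 * exp(-alpha * r^2)
    },
    potential = function(points) {
      r <- rdist(points)
      v <- numeric(length(r))
      small <- r < 1e-8
      v[small] <- n_electrons * 2 * sqrt(alpha / pi)
      ## erf via pnorm
      erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
      v[!small] <- n_electrons * erf(sqrt(alpha) * r[!small]) / r[!small]
      v
    },
    center = center, alpha = alpha, n_electrons = n_electrons
  )
}
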