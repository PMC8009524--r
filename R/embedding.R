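## Frozen-density-embedding potential machinery: nonadditive Thomas-Fermi /
## LDA potentials and energies, environment electrostatics, assembly of the
## total embedding potential on the grid, and its projection onto the active
## AO basis.

.check_same_grid <- function(a, b) {
  if (length(.rho_values(a)) != length(.rho_values(b))) {
    stop("densities live on different grids")
  }
}

#' Nonadditive embedding potentials
#'
#' v_nad[rho_I, rho_II] = v[rho_I + rho_II] - v[rho_I] for the kinetic
#' (Thomas-Fermi) and exchange-correlation (LDA) channels. This is the
#' functional derivative, with respect to the active density, of the
#' nonadditive energy at fixed environment density.
#'
#' @param rho_I active-subsystem density on the grid.
#' @param rho_II frozen environment density on the same grid.
#' @param f a [functional_set].
#' @return list with numeric vectors `v_nad_kin` and `v_nad_xc` (hartree).
#' @export
nonadditive_potential <- function(rho_I, rho_II, f = functional_set()) {
  .check_same_grid(rho_I, rho_II)
  r1 <- .rho_values(rho_I); r2 <- .rho_values(rho_II)
  rt <- r1 + r2
  list(v_nad_kin = tf_kinetic_potential(rt) - tf_kinetic_potential(r1),
       v_nad_xc = lda_xc_potential(rt) - lda_xc_potential(r1))
}

#' Nonadditive embedding energies
#'
#' X[rho_I + rho_II] - X[rho_I] - X[rho_II] by quadrature, for X the
#' Thomas-Fermi kinetic energy and the LDA XC energy.
#'
#' @inheritParams nonadditive_potential
#' @param weights quadrature weights of the common grid.
#' @return list with `E_nad_kin` and `E_nad_xc` (hartree).
#' @export
nonadditive_energy <- function(rho_I, rho_II, weights, f = functional_set()) {
  .check_same_grid(rho_I, rho_II)
  r1 <- .rho_values(rho_I); r2 <- .rho_values(rho_II)
  rt <- r1 + r2
  list(
    E_nad_kin = sum(weights * (tf_energy_density(rt) - tf_energy_density(r1) -
                                 tf_energy_density(r2))),
    E_nad_xc = sum(weights * (lda_xc_energy_density(rt) - lda_xc_energy_density(r1) -
                                lda_xc_energy_density(r2)))
  )
}

## Kernel of the embedding potential with respect to the active density,
## evaluated pointwise: d v_emb / d rho_I = f_xc[rho_tot] - f_xc[rho_I]
## + f_TF[rho_tot] - f_TF[rho_I].  Adding this to the bare f_xc[rho_I] of the
## LR solver reproduces, in the linear regime, the response of a propagation
## whose embedding potential tracks the instantaneous active density.
embedding_kernel <- function(rho_I, rho_II) {
  r1 <- .rho_values(rho_I); r2 <- .rho_values(rho_II)
  rt <- r1 + r2
  (lda_xc_kernel(rt) - lda_xc_kernel(r1)) + (tf_kernel(rt) - tf_kernel(r1))
}

#' Environment electrostatics on the grid
#'
#' The two frozen electrostatic pieces of the embedding potential:
#' `v_nuc_env(r_k) = -sum_A Z_A / |r_k - R_A|` and the Coulomb potential of
#' the frozen environment density. The latter is computed analytically from
#' the environment's basis-set representation of the density (attraction-type
#' integrals contracted with the density matrix), not by grid-on-grid
#' quadrature.
#'
#' @param env environment [subsystem].
#' @param env_D_ao environment AO density matrix (physical normalization), or
#'   a function `f(points)` returning the Coulomb potential directly (used by
#'   analytic model environments).
#' @param grid target `rt_grid`.
#' @return list with numeric vectors `v_nuc_env`, `v_coul_env` (hartree).
#' @export
environment_electrostatics <- function(env, env_D_ao, grid) {
  pts <- grid$points
  vnuc <- numeric(grid$n_points)
  for (ia in seq_along(env$Z)) {
    d <- sqrt(rowSums(sweep(pts, 2, env$coords[ia, ])^2))
    coincident <- d < 1e-6
    if (any(coincident)) {
      warning("grid point(s) coincident with an environment nucleus; regularized")
      d[coincident] <- 1e-6
    }
    vnuc <- vnuc - env$Z[ia] / d
  }
  vcoul <- if (is.function(env_D_ao)) {
    env_D_ao(pts)
  } else {
    esp_of_density(build_shells(env), env_D_ao, pts)
  }
  list(v_nuc_env = vnuc, v_coul_env = vcoul)
}

#' Project a grid potential onto the AO basis
#'
#' V_mu_nu = sum_k w_k chi_mu(r_k) v(r_k) chi_nu(r_k); the result is
#' symmetrized. Exactly linear in `v`.
#'
#' @param v potential values at the grid points (hartree).
#' @param aovals N x n_basis AO values.
#' @param weights quadrature weights.
#' @return real symmetric n_basis x n_basis matrix.
#' @export
project_potential_to_ao <- function(v, aovals, weights) {
  if (any(!is.finite(v))) stop("non-finite potential values")
  if (length(v) != nrow(aovals) || length(weights) != nrow(aovals)) {
    stop("dimension mismatch between potential, weights and AO values")
  }
  M <- crossprod(aovals, (weights * v) * aovals)
  (M + t(M)) / 2
}

#' Assemble the embedding potential
#'
#' Sums the four components in the fixed, documented order (environment
#' nuclear, environment Coulomb, nonadditive XC, nonadditive kinetic) and
#' projects the total onto the active AO basis.
#'
#' @param v_nuc_env,v_coul_env,v_nad_xc,v_nad_kin component vectors on a
#'   common grid.
#' @param aovals active-subsystem AO values on that grid.
#' @param weights quadrature weights.
#' @param step time-step index stamped on the object (0 for the ground
#'   state).
#' @return object of class `rt_embedding_potential` with the four components,
#'   their pointwise `total`, the projected `ao_matrix` and `timestamp_step`.
#' @export
assemble_embedding_potential <- function(v_nuc_env, v_coul_env, v_nad_xc,
                                         v_nad_kin, aovals, weights, step = 0L) {
  nlen <- length(v_nuc_env)
  if (length(v_coul_env) != nlen || length(v_nad_xc) != nlen ||
      length(v_nad_kin) != nlen) {
    stop("embedding-potential components have mismatched lengths")
  }
  total <- v_nuc_env + v_coul_env + v_nad_xc + v_nad_kin
  structure(list(
    v_nuc_env = v_nuc_env, v_coul_env = v_coul_env,
    v_nad_xc = v_nad_xc, v_nad_kin = v_nad_kin,
    total = total,
    ao_matrix = project_potential_to_ao(total, aovals, weights),
    timestamp_step = as.integer(step)
  ), class = "rt_embedding_potential")
}

#' @export
print.rt_embedding_potential <- function(x, ...) {
  cat(sprintf("<embedding potential on %d grid points (step %d); |V_ao|_max = %.3e>\n",
              length(x$total), x$timestamp_step, max(abs(x$ao_matrix))))
  invisible(x)
}

#' Write an embedding-potential grid dump
#'
#' Plain-text format, one line per point: `x y z w v_total v_nuc v_coul v_xc
#' v_kin` (atomic units) with a `#`-prefixed header.
#'
#' @param vemb an `rt_embedding_potential`.
#' @param grid the grid it lives on.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_dump <- function(vemb, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# embedding potential grid dump (atomic units)",
               sprintf("# n_points %d scope %s step %d", grid$n_points,
                       grid$scope, vemb$timestamp_step),
               "# x y z w v_total v_nuc v_coul v_xc v_kin"), con)
  m <- cbind(grid$points, grid$weights, vemb$total, vemb$v_nuc_env,
             vemb$v_coul_env, vemb$v_nad_xc, vemb$v_nad_kin)
  utils::write.table(format(m, digits = 12, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an embedding-potential grid dump
#' @param path file written by [write_grid_dump()].
#' @return list with `points`, `weights`, and the potential components.
#' @export
read_grid_dump <- function(path) {
  m <- unname(as.matrix(utils::read.table(path, comment.char = "#")))
  list(points = m[, 1:3, drop = FALSE], weights = m[, 4],
       total = m[, 5], v_nuc_env = m[, 6], v_coul_env = m[, 7],
       v_nad_xc = m[, 8], v_nad_kin = m[, 9])
}
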