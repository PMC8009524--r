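## Density-matrix propagation under the Liouville-von Neumann equation
## i dD/dt = [F(t), D] in the reference MO basis, using the second-order
## midpoint Magnus propagator U = exp(-i F(t+dt/2) dt) with an iterative
## predictor/corrector refinement of the midpoint Fock.

#' Propagation parameters
#'
#' @param dt time step (a.u.).
#' @param n_steps number of steps.
#' @param pc_tol predictor/corrector convergence threshold: max-norm of the
#'   density change between corrector iterates.
#' @param pc_max_iter corrector iteration cap (exceeding it is a hard error,
#'   the numerical-instability signal).
#' @param emb_update_stride steps between embedding-potential rebuilds;
#'   0 keeps the potential static at its t = 0 value.
#' @param record_stride record the dipole every this many steps.
#' @return list of class `rt_prop_config`.
#' @export
propagation_config <- function(dt = 0.1, n_steps = 1000, pc_tol = 1e-7,
                               pc_max_iter = 20, emb_update_stride = 1,
                               record_stride = 1) {
  if (dt == 0) stop("dt must be nonzero")
  if (pc_max_iter < 1) stop("pc_max_iter must be >= 1")
  if (emb_update_stride < 0 || record_stride < 1) stop("invalid stride")
  structure(list(dt = dt, n_steps = as.integer(n_steps), pc_tol = pc_tol,
                 pc_max_iter = as.integer(pc_max_iter),
                 emb_update_stride = as.integer(emb_update_stride),
                 record_stride = as.integer(record_stride)),
            class = "rt_prop_config")
}

#' Transform matrices between AO and MO representations
#'
#' Fock-type operators: F^MO = C^T F^AO C (and back with the metric,
#' F^AO = S C F^MO C^T S). Density-type matrices: D^AO = C D^MO C^T (and
#' back, D^MO = C^T S D^AO S C). The round trip is the identity and
#' tr(D^AO S) = tr(D^MO).
#'
#' @param M matrix to transform.
#' @param C reference MO coefficients, S-orthonormal.
#' @param S AO overlap matrix.
#' @param direction one of `"fock_ao_to_mo"`, `"fock_mo_to_ao"`,
#'   `"density_mo_to_ao"`, `"density_ao_to_mo"`.
#' @return transformed matrix.
#' @export
mo_ao_transform <- function(M, C, S, direction = c("fock_ao_to_mo",
                                                   "fock_mo_to_ao",
                                                   "density_mo_to_ao",
                                                   "density_ao_to_mo")) {
  direction <- match.arg(direction)
  if (max(abs(crossprod(C, S %*% C) - diag(ncol(C)))) > 1e-8) {
    stop("MO coefficients are not S-orthonormal")
  }
  switch(direction,
         fock_ao_to_mo = crossprod(C, M %*% C),
         fock_mo_to_ao = S %*% C %*% M %*% t(C) %*% S,
         density_mo_to_ao = C %*% M %*% t(C),
         density_ao_to_mo = crossprod(C, S %*% M %*% S %*% C))
}

#' One midpoint Magnus step
#'
#' D(t+dt) = U D U^dagger with U = exp(-i F_mid dt) via exact
#' eigendecomposition of the (Hermitian) midpoint Fock. Unitary by
#' construction: the spectrum of D is preserved.
#'
#' @param D density matrix (complex Hermitian).
#' @param F_mid midpoint Fock matrix (Hermitian; a deviation beyond 1e-10
#'   max-norm is an error, flagging a broken Fock build).
#' @param dt time step (a.u.), may be negative.
#' @return propagated density matrix.
#' @export
magnus_step <- function(D, F_mid, dt) {
  herm_err <- max(abs(F_mid - Conj(t(F_mid))))
  if (herm_err > 1e-10) {
    stop("non-Hermitian midpoint Fock (max deviation ", format(herm_err), ")")
  }
  e <- eigen((F_mid + Conj(t(F_mid))) / 2, symmetric = TRUE)
  ph <- exp(-1i * e$values * dt)
  U <- e$vectors %*% (ph * Conj(t(e$vectors)))
  U %*% D %*% Conj(t(U))
}

#' One predictor/corrector propagation step
#'
#' Iterates: propagate with the current midpoint-Fock guess, rebuild the
#' midpoint Fock from the interpolated density (D(t) + D(t+dt))/2 at the
#' midpoint time, repeat until the propagated density is stationary between
#' corrector iterates (max-norm below `pc_tol`). Converged, the scheme is
#' time-reversal symmetric.
#'
#' @param D current density matrix (MO basis, complex Hermitian).
#' @param t current time (a.u.).
#' @param dt time step.
#' @param fock_builder function `(D, t) -> Hermitian Fock` in the same basis.
#' @param F_guess initial midpoint-Fock guess (extrapolated by the caller;
#'   defaults to a fresh build at (D, t)).
#' @param pc_tol,pc_max_iter convergence control; exhausting `pc_max_iter`
#'   is an error reporting the last residual.
#' @return list: `D` (propagated), `F_mid` (converged midpoint Fock),
#'   `n_iter` (corrector iterations used).
#' @export
predictor_corrector_step <- function(D, t, dt, fock_builder, F_guess = NULL,
                                     pc_tol = 1e-7, pc_max_iter = 20) {
  F_mid <- if (is.null(F_guess)) fock_builder(D, t) else F_guess
  D_prev <- NULL
  for (it in seq_len(pc_max_iter)) {
    D_new <- magnus_step(D, F_mid, dt)
    if (!is.null(D_prev)) {
      res <- max(abs(D_new - D_prev))
      if (res < pc_tol) {
        return(list(D = D_new, F_mid = F_mid, n_iter = it))
      }
    }
    D_prev <- D_new
    F_mid <- fock_builder((D + D_new) / 2, t + dt / 2)
  }
  stop("predictor/corrector did not converge in ", pc_max_iter,
       " iterations (last residual ", format(max(abs(D_new - D_prev))), ")")
}

#' Propagate the (embedded) ground state under an external field
#'
#' Main real-time loop. The reference basis is the set of ground-state MOs
#' (polarized MOs for embedded runs, i.e. including the t = 0 embedding
#' potential). Per step the Kohn-Sham matrix
#' F(t) = T + v_nuc + J[rho(t)] + V_xc[rho(t)] + v_ext(t) (+ V_emb(t))
#' is rebuilt from the instantaneous density; for embedded runs the
#' nonadditive part of V_emb is recomputed from the instantaneous active
#' density every `emb_update_stride` steps (stride 0: held at its initial
#' value) while the environment electrostatics stay frozen. The recorded
#' dipole is mu_p(t) = -tr(D_phys P_p) plus the nuclear dipole, with origin
#' at the active subsystem's center of nuclear charge.
#'
#' @param gs an `rt_scf` (isolated run; any `v_extra` it was converged with
#'   is kept as a static extra operator) or an `rt_embedded_scf`.
#' @param field an [field_spec()].
#' @param cfg an [propagation_config()].
#' @param verbose print stage messages.
#' @return object of class `rt_dipole_trace`: `times`, `mu` (3 x n_records),
#'   `field` (3 x n_records), `trace_of_D`, `idem_drift`, `pc_iters`,
#'   `n_emb_rebuilds`, `rebuild_steps`, `mu0` (initial dipole), `dt`,
#'   `kick` (the field), and the final density `D_final`.
#' @export
propagate <- function(gs, field, cfg = propagation_config(), verbose = FALSE) {
  embedded <- inherits(gs, "rt_embedded_scf")
  egs <- if (embedded) gs else NULL
  gs <- if (embedded) egs$active_gs else gs
  sys <- gs$system
  ints <- sys$ints
  C <- gs$mo_coeffs
  n <- sys$n_basis

  Pmo <- lapply(ints$dipole, function(P) crossprod(C, P %*% C))
  nucdip <- nuclear_dipole(sys$spec, ints$origin)

  ## static extra operator (embedding at t0 or a fixed coupling)
  v_static <- gs$v_extra
  emb <- NULL
  if (embedded) {
    stride <- cfg$emb_update_stride
    emb <- list(
      aovals = sys$aovals, weights = egs$grid$weights,
      rho_II = egs$env_density, elec = egs$electrostatics,
      f = egs$functional_set, stride = stride
    )
    v_static <- egs$v_emb0$ao_matrix
  }

  v_held <- v_static
  rebuild_steps <- integer(0)

  fock_mo <- function(D_mo, t_mid) {
    Dr <- 2 * (C %*% Re(D_mo) %*% t(C))
    F <- ints$core_h + coulomb_matrix(sys, Dr) + xc_matrix(sys, Dr, energy = FALSE)$V
    if (!is.null(v_held)) F <- F + v_held
    Ef <- field_value(field, t_mid)[, 1]
    if (any(Ef != 0)) {
      F <- F + Ef[1] * ints$dipole$x + Ef[2] * ints$dipole$y + Ef[3] * ints$dipole$z
    }
    crossprod(C, F %*% C)
  }

  rebuild_vemb <- function(D_mo, step) {
    Dr <- 2 * (C %*% Re(D_mo) %*% t(C))
    rho_I <- density_on_grid(Dr, emb$aovals, egs$grid)
    nad <- nonadditive_potential(rho_I, emb$rho_II, emb$f)
    v <- emb$elec$v_nuc_env + emb$elec$v_coul_env + nad$v_nad_xc + nad$v_nad_kin
    project_potential_to_ao(v, emb$aovals, emb$weights)
  }

  ## initial state (+ analytic kick)
  D <- initial_density(gs)
  if (field$kind == "delta_kick" && field$kappa > 0) {
    D <- apply_delta_kick(D, field$kappa, field$direction, ints, C)
  }

  nrec <- cfg$n_steps %/% cfg$record_stride + 1L
  times <- numeric(nrec)
  mu <- matrix(0, 3, nrec)
  fld <- matrix(0, 3, nrec)
  trD <- numeric(nrec)
  idem <- numeric(nrec)
  pc_iters <- integer(cfg$n_steps)

  record <- function(k, t, D) {
    times[k] <<- t
    mu[, k] <<- -2 * vapply(Pmo, function(P) Re(sum(t(P) * D)), numeric(1)) + nucdip
    fld[, k] <<- field_value(field, t)[, 1]
    trD[k] <<- Re(sum(diag(D)))
    idem[k] <<- max(abs(D %*% D - D))
  }
  record(1L, 0, D)

  F_hist <- list()   # last two converged midpoint Focks for extrapolation
  k <- 1L
  for (s in seq_len(cfg$n_steps)) {
    t <- (s - 1L) * cfg$dt
    if (embedded && emb$stride >= 1L && (s - 1L) %% emb$stride == 0L) {
      v_held <- rebuild_vemb(D, s - 1L)
      rebuild_steps <- c(rebuild_steps, s - 1L)
      if (verbose) message(sprintf("[embed] rebuilt V_emb at step %d", s - 1L))
    }
    F_guess <- if (length(F_hist) == 2) {
      2 * F_hist[[2]] - F_hist[[1]]
    } else if (length(F_hist) == 1) {
      F_hist[[1]]
    } else {
      NULL
    }
    st <- predictor_corrector_step(D, t, cfg$dt, fock_mo, F_guess = F_guess,
                                   pc_tol = cfg$pc_tol,
                                   pc_max_iter = cfg$pc_max_iter)
    D <- st$D
    pc_iters[s] <- st$n_iter
    F_hist <- if (length(F_hist) == 0) list(st$F_mid) else list(F_hist[[length(F_hist)]], st$F_mid)
    if (!all(is.finite(Re(D)))) stop("non-finite density at step ", s)
    if (s %% cfg$record_stride == 0L) {
      k <- k + 1L
      record(k, s * cfg$dt, D)
      if (!all(is.finite(mu[, k]))) stop("non-finite dipole at step ", s)
    }
  }

  structure(list(
    times = times, mu = mu, field = fld, trace_of_D = trD, idem_drift = idem,
    pc_iters = pc_iters, n_emb_rebuilds = length(rebuild_steps),
    rebuild_steps = rebuild_steps, dt = cfg$dt, kick = field,
    n_occ = gs$n_occ, mu0 = mu[, 1], D_final = D, config = cfg
  ), class = "rt_dipole_trace")
}

#' @export
print.rt_dipole_trace <- function(x, ...) {
  cat(sprintf("<dipole trace: %d records over %.1f a.u., dt = %g>\n",
              length(x$times), max(x$times), x$dt))
  if (!is.null(x$n_occ)) {
    cat(sprintf("  max trace drift %.2e, max idempotency drift %.2e\n",
                max(abs(x$trace_of_D - x$n_occ)), max(x$idem_drift)))
  }
  invisible(x)
}

#' @export
plot.rt_dipole_trace <- function(x, component = 3, ...) {
  lab <- c("x", "y", "z")[component]
  graphics::plot(x$times, x$mu[component, ] - x$mu0[component], type = "l",
                 xlab = "t (a.u.)", ylab = bquote(mu[.(lab)] - mu[.(lab)](0) ~ "(a.u.)"), ...)
  invisible(x)
}

#' Write a dipole trace to a plain-text file
#'
#' Columns: `step time mu_x mu_y mu_z E_x E_y E_z trace_re`, atomic units,
#' with a `#` header echoing the propagation configuration.
#'
#' @param trace an `rt_dipole_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dipole_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfgline <- sprintf("# dt %g n_steps %d pc_tol %g emb_update_stride %d record_stride %d",
                     trace$dt, trace$config$n_steps, trace$config$pc_tol,
                     trace$config$emb_update_stride, trace$config$record_stride)
  writeLines(c("# rtfde dipole trace (atomic units)", cfgline,
               "# step time mu_x mu_y mu_z E_x E_y E_z trace_re"), con)
  step <- round(trace$times / trace$dt)
  m <- cbind(step, trace$times, t(trace$mu), t(trace$field), trace$trace_of_D)
  utils::write.table(format(m, digits = 15), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dipole trace written by [write_dipole_trace()]
#' @param path input path.
#' @return a reduced `rt_dipole_trace` (times, mu, field, trace).
#' @export
read_dipole_trace <- function(path) {
  m <- unname(as.matrix(utils::read.table(path, comment.char = "#")))
  structure(list(times = m[, 2], mu = t(m[, 3:5, drop = FALSE]),
                 field = t(m[, 6:8, drop = FALSE]), trace_of_D = m[, 9],
                 dt = if (nrow(m) > 1) m[2, 2] - m[1, 2] else NA_real_,
                 mu0 = m[1, 3:5]),
            class = "rt_dipole_trace")
}
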