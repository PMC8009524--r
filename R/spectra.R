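## Spectral analysis of dipole traces: Pade-accelerated Fourier transforms,
## dipole strength functions S(omega), HHG power spectra and the
## semiclassical cutoff estimate.

#' Pade-accelerated Fourier transform of a real signal
#'
#' Represents the Z-transform of the exponentially damped signal as a
#' diagonal rational approximant A(z)/B(z) of order floor(N/2), with the
#' denominator obtained from a least-squares Toeplitz solve, and evaluates it
#' on the requested frequency grid. This resolves line positions far below
#' the 2 pi / T grid limit of the plain discrete transform. If the Toeplitz
#' system is numerically singular the plain damped discrete sum is returned
#' with a warning.
#'
#' Signals longer than `2 * max_order + 1` points are decimated (every k-th
#' sample) to cap the solve order; with the spectral window of interest far
#' below the Nyquist frequency this is lossless in practice.
#'
#' @param signal real time series sampled every `dt` starting at t = 0.
#' @param dt sampling interval (a.u.).
#' @param omega_grid frequencies to evaluate (a.u.).
#' @param gamma damping constant (a.u.); the signal is multiplied by
#'   exp(-gamma t).
#' @param max_order cap on the Pade order.
#' @return complex vector: the approximated integral of signal(t) e^{i w t}
#'   over the sampled window.
#' @export
pade_fourier <- function(signal, dt, omega_grid, gamma = 1e-4,
                         max_order = 1200) {
  N <- length(signal)
  if (N < 4) stop("signal too short")
  if (gamma < 0) stop("gamma must be >= 0")
  tt <- (seq_len(N) - 1) * dt
  d <- signal * exp(-gamma * tt)
  if (all(d == 0)) return(complex(real = numeric(length(omega_grid))))

  decim <- ceiling(N / (2 * max_order + 1))
  if (decim > 1) {
    idx <- seq(1, N, by = decim)
    d <- d[idx]
    dt <- dt * decim
    N <- length(d)
  }
  M <- (N - 1) %/% 2
  d <- d[seq_len(2 * M + 1)]

  ## b_0 = 1; sum_{m=1}^{M} b_m d_{k-m} = -d_k for k = M+1 .. 2M
  G <- matrix(0, M, M)
  for (k in seq_len(M)) G[k, ] <- d[(M + k) - seq_len(M) + 1]
  rhs <- -d[M + 1 + seq_len(M)]
  b <- tryCatch(qr.solve(G, rhs, tol = 1e-14), error = function(e) NULL)
  if (is.null(b)) {
    ## rank-deficient Toeplitz (e.g. a signal with few spectral lines):
    ## minimum-norm least-squares solution via the SVD pseudo-inverse
    b <- tryCatch({
      sv <- svd(G)
      pos <- sv$d > 1e-12 * sv$d[1]
      sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
    }, error = function(e) NULL)
  }
  if (is.null(b)) {
    warning("singular Pade system; falling back to the plain discrete transform")
    tt <- (seq_len(length(d)) - 1) * dt
    return(vapply(omega_grid,
                  function(w) dt * sum(d * exp(1i * w * tt)),
                  complex(1)))
  }
  b <- as.vector(b)
  bfull <- c(1, b)
  ## a_k = sum_{m=0}^{k} b_m d_{k-m}, k = 0..M
  a <- vapply(0:M, function(k) {
    m <- 0:min(k, M)
    sum(bfull[m + 1] * d[k - m + 1])
  }, numeric(1))

  z <- exp(1i * omega_grid * dt)
  horner <- function(cf) {
    acc <- rep(cf[length(cf)] + 0i, length(z))
    for (j in rev(seq_len(length(cf) - 1))) acc <- acc * z + cf[j]
    acc
  }
  dt * horner(a) / horner(bfull)
}

#' Dipole strength function from three delta-kick traces
#'
#' Computes the diagonal polarizabilities alpha_pp(omega) as the (damped,
#' Pade-accelerated) Fourier transform of the induced dipole divided by the
#' kick strength, and
#' S(omega) = (2 omega / 3 pi) sum_p Im alpha_pp(omega),
#' whose peak positions are the electronic excitation energies.
#'
#' @param traces list of three `rt_dipole_trace` objects from kicks along
#'   x, y, z (in that order). A single trace is accepted for a
#'   one-direction S_p(omega).
#' @param kappa kick strength used in the runs (a.u.).
#' @param gamma damping (a.u.).
#' @param omega_grid frequency grid (a.u.).
#' @param max_order Pade order cap, passed to [pade_fourier()].
#' @return object of class `rt_spectrum`: `omega`, `energy_ev`, `S`,
#'   `alpha_diag` (list of complex vectors), `gamma`, `method`.
#' @export
strength_function <- function(traces, kappa, gamma = 1e-4,
                              omega_grid = seq(1e-4, 1.0, by = 1e-4),
                              max_order = 1200) {
  if (inherits(traces, "rt_dipole_trace")) traces <- list(traces)
  if (kappa <= 0) stop("kappa must be > 0")
  t0 <- traces[[1]]$times
  for (tr in traces) {
    if (length(tr$times) != length(t0) || max(abs(tr$times - t0)) > 1e-10) {
      stop("traces have mismatched time grids")
    }
  }
  dt <- t0[2] - t0[1]
  dirs <- if (length(traces) == 3) 1:3 else
    which.max(abs(traces[[1]]$kick$direction))
  alpha <- vector("list", length(traces))
  Ssum <- numeric(length(omega_grid))
  for (j in seq_along(traces)) {
    p <- dirs[j]
    mu_ind <- traces[[j]]$mu[p, ] - traces[[j]]$mu[p, 1]
    alpha[[j]] <- pade_fourier(mu_ind, dt, omega_grid, gamma = gamma,
                               max_order = max_order) / kappa
    Ssum <- Ssum + Im(alpha[[j]])
  }
  structure(list(omega = omega_grid, energy_ev = omega_grid * HARTREE_EV,
                 S = (2 * omega_grid / (3 * pi)) * Ssum,
                 alpha_diag = alpha, gamma = gamma, method = "pade"),
            class = "rt_spectrum")
}

#' Locate peaks of a spectrum
#'
#' Local maxima above a height threshold, returned in ascending frequency.
#'
#' @param spec an `rt_spectrum` (or list with `omega` and `S`).
#' @param n_peaks maximum number of peaks to return.
#' @param min_height_frac discard maxima below this fraction of the largest.
#' @return data frame with `omega`, `energy_ev`, `height`.
#' @export
find_spectrum_peaks <- function(spec, n_peaks = 10, min_height_frac = 0.005) {
  S <- spec$S
  om <- spec$omega
  i <- which(diff(sign(diff(S))) == -2) + 1
  if (length(i) == 0) return(data.frame(omega = numeric(0), energy_ev = numeric(0), height = numeric(0)))
  i <- i[S[i] > min_height_frac * max(S[i])]
  i <- utils::head(i, n_peaks)
  data.frame(omega = om[i], energy_ev = om[i] * HARTREE_EV, height = S[i])
}

#' High-harmonic-generation power spectrum
#'
#' P(omega) = |integral_0^tau mu(t) e^{-i omega t} dt|^2 by plain discrete
#' quadrature over the pulse window (rectangular truncation at tau; no
#' apodization, no Pade), reported against harmonic order omega / omega0.
#'
#' @param trace an `rt_dipole_trace` from a laser-driven run.
#' @param omega0 carrier frequency (a.u.).
#' @param tau integration window end (a.u.); must not exceed the trace.
#' @param axis polarization axis (1 = x, 2 = y, 3 = z).
#' @param max_harmonic highest harmonic order on the output grid.
#' @param d_order grid spacing in harmonic orders.
#' @return object of class `rt_hhg`: `omega`, `harmonic_orders`, `power`,
#'   `log10_P`, `window`.
#' @export
hhg_spectrum <- function(trace, omega0, tau, axis = 3, max_harmonic = 40,
                         d_order = 0.02) {
  if (tau <= 0) stop("tau must be > 0")
  spacing <- trace$times[2] - trace$times[1]
  if (tau > max(trace$times) + spacing) stop("window end exceeds the trace")
  sel <- trace$times <= tau
  tt <- trace$times[sel]
  mu <- trace$mu[axis, sel] - trace$mu[axis, 1]
  dt <- tt[2] - tt[1]
  orders <- seq(d_order, max_harmonic, by = d_order)
  om <- orders * omega0
  ft <- vapply(om, function(w) dt * sum(mu * exp(-1i * w * tt)), complex(1))
  P <- Mod(ft)^2
  structure(list(omega = om, harmonic_orders = orders, power = P,
                 log10_P = log10(pmax(P, 1e-300)), window = c(0, tau),
                 omega0 = omega0),
            class = "rt_hhg")
}

#' Semiclassical HHG cutoff estimate
#'
#' U_p = E^2 / (4 omega0^2); E_cutoff = I_p + 3.17 U_p; N_max = E_cutoff /
#' omega0 (the three-step-model cutoff law).
#'
#' @param E peak field strength (a.u.).
#' @param omega0 carrier frequency (a.u.).
#' @param I_p ionization potential (a.u.).
#' @return object of class `rt_cutoff`: `U_p`, `E_cutoff` (a.u.), `N_max`.
#' @export
cutoff_estimate <- function(E, omega0, I_p) {
  if (omega0 <= 0) stop("omega0 must be > 0")
  if (E < 0 || I_p < 0) stop("E and I_p must be >= 0")
  U_p <- E^2 / (4 * omega0^2)
  E_cutoff <- I_p + 3.17 * U_p
  structure(list(U_p = U_p, E_cutoff = E_cutoff, N_max = E_cutoff / omega0),
            class = "rt_cutoff")
}

#' @export
print.rt_cutoff <- function(x, ...) {
  cat(sprintf("<HHG cutoff: U_p = %.5f a.u., E_cutoff = %.5f a.u., N_max = %.2f>\n",
              x$U_p, x$E_cutoff, x$N_max))
  invisible(x)
}

#' @export
print.rt_spectrum <- function(x, ...) {
  pk <- find_spectrum_peaks(x, n_peaks = 5)
  cat(sprintf("<dipole strength function on [%.3f, %.3f] a.u., gamma = %g>\n",
              min(x$omega), max(x$omega), x$gamma))
  if (nrow(pk)) {
    cat("  leading peaks (eV):", paste(sprintf("%.3f", pk$energy_ev), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.rt_spectrum <- function(x, ...) {
  graphics::plot(x$energy_ev, x$S, type = "l", xlab = "energy (eV)",
                 ylab = expression(S(omega) ~ "(a.u.)"), ...)
  invisible(x)
}

#' @export
plot.rt_hhg <- function(x, ...) {
  graphics::plot(x$harmonic_orders, x$log10_P, type = "l",
                 xlab = expression(omega / omega[0]),
                 ylab = expression(log[10] ~ P(omega)), ...)
  invisible(x)
}

#' Write a spectrum to a plain-text file
#'
#' Strength functions: columns `omega_au energy_ev S`. HHG spectra: columns
#' `omega_au harmonic_order log10P`. `#` header lines carry parameters.
#'
#' @param spec an `rt_spectrum` or `rt_hhg`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(spec, "rt_hhg")) {
    writeLines(c(sprintf("# rtfde HHG spectrum; omega0 %.8f window %.1f",
                         spec$omega0, spec$window[2]),
                 "# omega_au harmonic_order log10P"), con)
    m <- cbind(spec$omega, spec$harmonic_orders, spec$log10_P)
  } else {
    writeLines(c(sprintf("# rtfde dipole strength function; gamma %g", spec$gamma),
                 "# omega_au energy_ev S"), con)
    m <- cbind(spec$omega, spec$energy_ev, spec$S)
  }
  utils::write.table(format(m, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
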