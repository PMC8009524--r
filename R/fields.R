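## External field specifications: impulsive delta kicks (applied analytically
## as a unitary boost) and cos^2-envelope laser pulses.

#' Specify the external electric field
#'
#' Two kinds are supported. `delta_kick`: an impulsive field
#' E(t) = kappa delta(t) n, applied analytically at t = 0 as the unitary
#' boost exp(-i kappa P_n) of the ground-state density (probing all dipole
#' excitations at once). `cos2_pulse`: a laser pulse
#' E(t) = E0 cos^2(pi (t - tau/2) / tau) sin(omega0 t) n on 0 <= t <= tau,
#' zero outside, with envelope width tau = n_cycles * 2 pi / omega0 unless
#' overridden.
#'
#' @param kind `"delta_kick"` or `"cos2_pulse"`.
#' @param direction 3-vector, normalized internally.
#' @param kappa kick strength (a.u.).
#' @param E0 peak field amplitude (a.u.).
#' @param omega0 carrier frequency (a.u.).
#' @param n_cycles number of optical cycles under the envelope.
#' @param tau explicit envelope width (a.u.), overriding the default.
#' @return object of class `rt_field`.
#' @export
field_spec <- function(kind = c("delta_kick", "cos2_pulse"),
                       direction = c(0, 0, 1), kappa = 1e-5,
                       E0 = 0, omega0 = NULL, n_cycles = NULL, tau = NULL) {
  kind <- match.arg(kind)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("field direction must be nonzero")
  direction <- direction / nrm
  if (kind == "delta_kick") {
    if (kappa < 0) stop("kappa must be >= 0")
    return(structure(list(kind = kind, direction = direction, kappa = kappa),
                     class = "rt_field"))
  }
  if (is.null(omega0) || is.null(E0)) stop("cos2_pulse needs E0 and omega0")
  if (E0 < 0) stop("E0 must be >= 0")
  if (is.null(tau)) {
    if (is.null(n_cycles)) stop("cos2_pulse needs n_cycles (or explicit tau)")
    tau <- n_cycles * 2 * pi / omega0
  }
  structure(list(kind = kind, direction = direction, E0 = E0,
                 omega0 = omega0, n_cycles = n_cycles, tau = tau),
            class = "rt_field")
}

#' Evaluate the field at time t
#'
#' For a delta kick this is zero for all t > 0 (the kick acts through
#' [apply_delta_kick()]).
#'
#' @param f an `rt_field`.
#' @param t time (a.u.), scalar or vector.
#' @return 3 x length(t) matrix of field components (a.u.).
#' @export
field_value <- function(f, t) {
  t <- as.numeric(t)
  amp <- if (f$kind == "delta_kick") {
    numeric(length(t))
  } else {
    a <- f$E0 * cos(pi * (t - f$tau / 2) / f$tau)^2 * sin(f$omega0 * t)
    a[t < 0 | t > f$tau] <- 0
    a
  }
  outer(f$direction, amp)
}

#' Apply an analytic delta kick to the MO density matrix
#'
#' D(0+) = W D W^dagger with W = exp(-i kappa P_n^MO),
#' P_n^MO = C^T (n . P^AO) C. Unitary, so trace and idempotency are
#' preserved exactly.
#'
#' @param D0 MO density matrix (the ground-state projector).
#' @param kappa kick strength (a.u.).
#' @param direction kick direction (3-vector, normalized internally).
#' @param basis an `rt_ao_basis` (for the dipole matrices).
#' @param C reference MO coefficients.
#' @return kicked complex MO density matrix.
#' @export
apply_delta_kick <- function(D0, kappa, direction, basis, C) {
  direction <- direction / sqrt(sum(direction^2))
  if (kappa == 0) return(D0 + 0i)
  Pao <- direction[1] * basis$dipole$x + direction[2] * basis$dipole$y +
    direction[3] * basis$dipole$z
  Pmo <- crossprod(C, Pao %*% C)
  e <- eigen((Pmo + t(Pmo)) / 2, symmetric = TRUE)
  W <- e$vectors %*% (exp(-1i * kappa * e$values) * t(e$vectors))
  W %*% D0 %*% Conj(t(W))
}
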