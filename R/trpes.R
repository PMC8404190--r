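#' Delay/energy grid for the photoelectron signal
#'
#' @param delays pump-probe delays (fs), uniform, strictly increasing.
#' @param energies photoelectron energies (eV), uniform, strictly increasing.
#' @export
signal_grid <- function(delays, energies) {
  check_uniform(delays, "signal_grid (delays)")
  check_uniform(energies, "signal_grid (energies)")
  structure(list(delays = delays, energies = energies), class = "signal_grid")
}

ion_veff <- function(model, ref_ev) model$I1 - ev_to_au(ref_ev)

default_ion_ref <- function(model) au_to_ev(min(model$I1))

#' Precompute the ion-surface Gram band of a trajectory
#'
#' The first-order photoelectron signal is a quadratic form in the
#' two-time overlaps `G(tau, j) = <U^tau g_j | g_{j+tau}>`, where `g_j`
#' are the ionization-source snapshots of the trajectory and `U` the
#' split-operator step on the ionized surface.  This band depends only on
#' the trajectory and the model, not on the probe; computing it once makes
#' every subsequent spectrogram (any pulse or train, any delay/energy
#' grid) a cheap post-processing step.
#'
#' @param model a `diabatic_model`.
#' @param traj a [propagate()] trajectory with `collect_source = TRUE`.
#' @param max_lag_fs largest two-time separation retained (fs).  Envelope
#'   pair weights at lag `tau` are at most `exp(-tau^2/(4 sigma_t^2))`, so
#'   6 envelope sigmas of the widest intended probe keeps the truncation
#'   below 1e-4.
#' @param ref_ev constant energy (eV) subtracted from the ionized surface
#'   so that ion-surface phases stay slow; any fixed value is exact, the
#'   default uses the surface minimum.
#' @return Object of class `ion_gram` for [spectrogram()].
#' @export
ion_gram <- function(model, traj, max_lag_fs, ref_ev = default_ion_ref(model)) {
  if (is.null(traj$source))
    stop("ion_gram: trajectory has no source samples (collect_source = TRUE)")
  g <- model$grid
  dt <- fs_to_au(traj$src_dt)
  L <- min(ncol(traj$source) - 1L, as.integer(ceiling(fs_to_au(max_lag_fs) / dt)))
  G <- cpp_band_gram(traj$source, ion_veff(model, ref_ev),
                     g$masses[1], g$masses[2], g$d1, g$d2, g$k1, g$k2,
                     dt, L)
  structure(list(G = G, src_times = traj$src_times, src_dt = traj$src_dt,
                 max_lag_fs = L * traj$src_dt, ref_ev = ref_ev),
            class = "ion_gram")
}

probe_sigma_t <- function(probe) probe$sigma_t

#' Photoelectron signal at one delay and energy
#'
#' Direct route: solves the driven ion-surface equation
#' `i dpsi_I/dt = (T + I1 + omega_p - omega_X) psi_I + mu E(t - T) psi_V(t)`
#' in the rotating frame, with the source drawing coherently from both
#' valence components (both ionize to the same ion surface), and returns
#' the final `||psi_I||^2` -- the integrated photoelectron current into
#' that energy bin.  First order: the valence trajectory is never
#' depleted.  [spectrogram()] computes the same quantity through the Gram
#' band; this direct route is kept as the independent slow path and for
#' spot checks.
#'
#' @param model a `diabatic_model`.
#' @param traj trajectory with source samples covering
#'   `[T - 4 sigma_t, T + 4 sigma_t]` (clipped at the pump time, before
#'   which no excited-state amplitude exists).
#' @param probe a [gaussian_pulse()] or [apt_spec()].
#' @param T pump-probe delay (fs).
#' @param omega_p photoelectron energy (eV), non-negative.
#' @export
ionization_amplitude <- function(model, traj, probe, T, omega_p) {
  if (omega_p < 0) stop("ionization_amplitude: omega_p must be >= 0")
  if (is.null(traj$source)) stop("ionization_amplitude: trajectory has no source samples")
  st <- traj$src_times
  s4 <- 4 * probe_sigma_t(probe)
  if (st[1] > max(T - s4, traj$t0) + 1e-9 || st[length(st)] < T + s4 - 1e-9)
    stop("ionization_amplitude: trajectory does not cover the probe window")
  sel <- which(st >= T - s4 & st <= T + s4)
  ref <- default_ion_ref(model)
  omega_tilde <- ev_to_au(omega_p - probe$omega_X + ref)
  w <- field_envelope(probe, st[sel] - T) *
    exp(1i * omega_tilde * fs_to_au(st[sel]))
  g <- model$grid
  dt <- fs_to_au(traj$src_dt)
  # the kernel accumulates -i dt w_k g_k per step, so its norm^2 already
  # carries the dt^2 of the time integral
  cpp_source_signal(traj$source[, sel, drop = FALSE], w,
                    ion_veff(model, ref),
                    g$masses[1], g$masses[2], g$d1, g$d2, g$k1, g$k2, dt)
}

#' Compute the photoelectron spectrogram
#'
#' Evaluates the first-order signal `S(T, omega_p)` on the full
#' delay/energy grid via the precomputed ion-surface Gram band: for each
#' delay the probe envelope weights the band diagonals, and the
#' photoelectron energy enters as a pure phase across the band.  The
#' result is deterministic (bit-for-bit for fixed inputs) and normalized
#' to unit maximum by default (plots are in arbitrary units).
#'
#' @inheritParams ionization_amplitude
#' @param sgrid a [signal_grid()].
#' @param gram optional precomputed [ion_gram()] (reused across probes);
#'   computed on the fly when absent.
#' @param normalize scale so `max(S) = 1` (the factor is recorded).
#' @return Object of class `spectrogram`: matrix `S` (delays x energies),
#'   the axes, the probe, and the normalization record.
#' @export
spectrogram <- function(model, traj, probe, sgrid, gram = NULL,
                        normalize = TRUE) {
  stopifnot(inherits(sgrid, "signal_grid"))
  sig_t <- probe_sigma_t(probe)
  if (is.null(gram))
    gram <- ion_gram(model, traj, max_lag_fs = 6 * sig_t)
  if (gram$max_lag_fs < 4 * sig_t - 1e-9)
    warning("spectrogram: Gram band narrower than 4 probe sigmas; signal truncated")
  st <- gram$src_times
  Tv <- sgrid$delays
  s4 <- 4 * sig_t
  if (st[1] > min(Tv) + 1e-9 || st[length(st)] < max(Tv) + s4 - 1e-9)
    stop("spectrogram: trajectory source does not cover the delay grid plus probe window")

  G <- gram$G
  L <- nrow(G) - 1L
  ns <- ncol(G)
  dt <- fs_to_au(gram$src_dt)
  omega_tilde <- ev_to_au(sgrid$energies - probe$omega_X + gram$ref_ev)
  # phase factors exp(i omega_tilde tau dt), eps_tau = 1 (tau = 0) else 2
  P <- exp(1i * outer(omega_tilde, (0:L) * dt))
  P[, -1] <- 2 * P[, -1]

  D <- matrix(0i, length(Tv), L + 1L)
  for (it in seq_along(Tv)) {
    env <- field_envelope(probe, st - Tv[it])
    cenv <- Conj(env)
    for (tau in 0:L) {
      j <- seq_len(ns - tau)
      D[it, tau + 1L] <- sum(cenv[j] * env[j + tau] * G[tau + 1L, j])
    }
  }
  S <- dt^2 * Re(D %*% t(P))
  S[S < 0] <- 0   # truncation can leave tiny negative residuals
  norm_rec <- list(normalized = normalize, max_raw = max(S))
  if (normalize && norm_rec$max_raw > 0) S <- S / norm_rec$max_raw
  structure(list(S = S, delays = Tv, energies = sgrid$energies,
                 probe = probe, normalization = norm_rec),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d delays in [%.3g, %.3g] fs x %d energies in [%.3g, %.3g] eV, max raw %.3e\n",
              length(x$delays), min(x$delays), max(x$delays),
              length(x$energies), min(x$energies), max(x$energies),
              x$normalization$max_raw))
  invisible(x)
}
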