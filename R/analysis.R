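#' Population traces of a trajectory
#'
#' Diabatic populations (and the absorbed norm) are recorded at every
#' propagation step; adiabatic populations are obtained by rotating each
#' stored snapshot into the local eigenbasis of the 2x2 diabatic
#' potential matrix.
#'
#' @param traj a [propagate()] trajectory.
#' @param model the `diabatic_model` it was propagated on.
#' @return List with `diabatic` (data.frame `t, P0, P1, absorbed`, per
#'   step) and `adiabatic` (data.frame `t, P_lower, P_upper`, per
#'   snapshot).
#' @export
populations <- function(traj, model) {
  rot <- adiabatic_rotation(model)
  ns <- length(traj$snap_times)
  dV <- model$grid$d1 * model$grid$d2
  P_lower <- P_upper <- numeric(ns)
  for (i in seq_len(ns)) {
    lo <- rot$c0_lo * traj$snap0[, , i] + rot$c1_lo * traj$snap1[, , i]
    up <- rot$c0_up * traj$snap0[, , i] + rot$c1_up * traj$snap1[, , i]
    P_lower[i] <- sum(abs(lo)^2) * dV
    P_upper[i] <- sum(abs(up)^2) * dV
  }
  list(diabatic = traj$pops,
       adiabatic = data.frame(t = traj$snap_times,
                              P_lower = P_lower, P_upper = P_upper))
}

# Pointwise eigenvector coefficients of [[V0, W], [W, V1]]: the lower
# adiabatic component is c0_lo * psi0 + c1_lo * psi1 and likewise for the
# upper.  Built from the half-angle of atan2(2W, V1 - V0), which keeps the
# coefficients continuous through the W -> 0 limit away from the seam.
adiabatic_rotation <- function(model) {
  th <- 0.5 * atan2(2 * model$W, model$V1 - model$V0)
  # eigenvalues mean -/+ r; lower eigenvector (cos th, -sin th),
  # upper (sin th, cos th)
  list(c0_lo = cos(th), c1_lo = -sin(th), c0_up = sin(th), c1_up = cos(th))
}

#' Electronic coherence magnitude
#'
#' Magnitude of the interstate nuclear overlap
#' `|<psi_lower(t) | psi_upper(t)>|` between the adiabatic components of
#' each snapshot: the quantity whose phase beats at the local energy gap
#' and whose magnitude decays as the branched packets separate.
#'
#' @inheritParams populations
#' @return data.frame with columns `t` (fs) and `coherence`.
#' @export
coherence_trace <- function(traj, model) {
  rot <- adiabatic_rotation(model)
  ns <- length(traj$snap_times)
  dV <- model$grid$d1 * model$grid$d2
  coh <- numeric(ns)
  for (i in seq_len(ns)) {
    lo <- rot$c0_lo * traj$snap0[, , i] + rot$c1_lo * traj$snap1[, , i]
    up <- rot$c0_up * traj$snap0[, , i] + rot$c1_up * traj$snap1[, , i]
    coh[i] <- Mod(sum(Conj(lo) * up)) * dV
  }
  data.frame(t = traj$snap_times, coherence = coh)
}

#' Onset time of a nonnegative trace
#'
#' First time a series exceeds `threshold` times its global maximum, with
#' linear interpolation between samples.  Returns `NA` ("no onset") when
#' the threshold is never exceeded.  This operationalizes the visual
#' "signal appears around t" reading of population and modulation traces.
#'
#' @param times time axis (fs).
#' @param values nonnegative trace.
#' @param threshold fraction of the global maximum (default 0.05).
#' @export
onset_time <- function(times, values, threshold = 0.05) {
  if (length(times) != length(values)) stop("onset_time: length mismatch")
  if (any(values < 0)) stop("onset_time: trace must be nonnegative")
  cut <- threshold * max(values)
  if (cut <= 0 || !any(values > cut)) return(NA_real_)
  i <- which(values > cut)[1]
  if (i == 1) return(times[1])
  times[i - 1] + (cut - values[i - 1]) / (values[i] - values[i - 1]) *
    (times[i] - times[i - 1])
}

#' Photoelectron band peaks at one delay
#'
#' Local maxima of the energy slice `S(T, .)` above a relative threshold,
#' with parabolic sub-bin interpolation; adjacent-peak separations are
#' attached as attribute `separations`.
#'
#' @param spectro a [spectrogram()].
#' @param T delay (fs); the nearest delay sample is used.
#' @param threshold relative height cut (default 0.05 of the slice max).
#' @export
band_peaks <- function(spectro, T, threshold = 0.05) {
  it <- which.min(abs(spectro$delays - T))
  slice <- spectro$S[it, ]
  pk <- comb_peaks(data.frame(energy = spectro$energies,
                              power = slice / max(slice, 1e-300)),
                   threshold = threshold)
  pk$height <- pk$height * max(slice)
  attr(pk, "separations") <- if (nrow(pk) > 1) diff(sort(pk$energy)) else numeric()
  pk
}

#' Strongest photoelectron bands of a spectrogram
#'
#' Ranks energy bands by time-integrated intensity and returns the `k`
#' most intense band centers (eV), e.g. the "three most intense peaks" of
#' a harmonic-comb spectrogram.
#'
#' @param spectro a [spectrogram()].
#' @param k number of bands to keep.
#' @param threshold relative peak threshold on the time-integrated slice.
#' @export
top_bands <- function(spectro, k = 3, threshold = 0.01) {
  prof <- colMeans(spectro$S)
  pk <- comb_peaks(data.frame(energy = spectro$energies,
                              power = prof / max(prof)),
                   threshold = threshold)
  if (!nrow(pk)) return(numeric())
  pk <- pk[order(-pk$height), ]
  sort(utils::head(pk$energy, k))
}

#' Delay-domain modulation analysis of a photoelectron band
#'
#' Integrates the signal over an energy window, removes the slow
#' population-driven drift with a moving average, and characterizes the
#' residual quantum-beat oscillation.
#'
#' The dominant beat frequency is read from the discrete Fourier
#' transform of the detrended trace over its second half (where the gap
#' has settled).  The onset is the start of *sustained* oscillation at
#' that frequency: the first zero crossing of the detrended trace that is
#' followed by at least `sustain` consecutive half-periods, each within
#' `tol_frac` of the dominant half-period.  Slow single-swing transients
#' from the population transfer have much longer crossing intervals and
#' are thereby excluded -- an amplitude threshold alone cannot separate
#' them from genuine beats in a deterministic, noise-free trace.  The
#' modulation depth is the post-onset peak-to-peak amplitude of the
#' detrended oscillation relative to twice the mean band intensity --
#' the residual band drift would otherwise contaminate a raw
#' `(max - min)/(max + min)` reading.
#'
#' @param spectro a [spectrogram()].
#' @param band length-2 energy window (eV).
#' @param detrend_window_fs moving-average window; default two IR
#'   half-periods of the 0.5 eV fundamental (twice the beat period of a
#'   1 eV gap).
#' @param sustain number of consecutive conforming half-periods required.
#' @param tol_frac relative tolerance on the half-period.
#' @return List with `onset_fs`, `frequency_ev`, `depth`, and the
#'   band-integrated trace as data.frame `trace`.
#' @export
modulation_analysis <- function(spectro, band, detrend_window_fs = 8.27,
                                sustain = 4L, tol_frac = 0.4) {
  sel <- spectro$energies >= band[1] & spectro$energies <= band[2]
  if (!any(sel)) stop("modulation_analysis: band outside the energy axis")
  s <- rowSums(spectro$S[, sel, drop = FALSE])
  tv <- spectro$delays
  dt <- tv[2] - tv[1]
  span <- tv[length(tv)] - tv[1]
  if (span < 2 * detrend_window_fs)
    stop("modulation_analysis: delay span shorter than two oscillation periods")
  hw <- max(1L, round(detrend_window_fs / dt / 2))
  trend <- stats::filter(s, rep(1 / (2 * hw + 1), 2 * hw + 1), sides = 2)
  trend <- fill_ends(as.numeric(trend))
  d <- s - trend

  # dominant frequency over the settled second half of the delay range
  late <- tv >= tv[1] + span / 2
  dd <- d[late] - mean(d[late])
  n <- length(dd)
  sp <- Mod(stats::fft(dd))^2
  f <- seq(0, n - 1) / (n * dt)               # cycles / fs
  half_bins <- 2:floor(n / 2)
  fstar <- f[half_bins][which.max(sp[half_bins])]
  freq <- 2 * pi * fstar * HBAR_EV_FS         # eV
  half_period <- 1 / (2 * fstar)

  # zero crossings of the detrended trace (linear interpolation)
  zc <- numeric()
  for (i in seq_len(length(d) - 1)) {
    if (is.finite(d[i]) && is.finite(d[i + 1]) &&
        d[i] != 0 && sign(d[i]) != sign(d[i + 1]))
      zc <- c(zc, tv[i] + dt * d[i] / (d[i] - d[i + 1]))
  }
  onset <- NA_real_
  if (length(zc) > sustain) {
    iv <- diff(zc)
    ok <- abs(iv - half_period) <= tol_frac * half_period
    run <- rle(ok)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1
    hit <- which(run$values & run$lengths >= sustain)
    if (length(hit)) onset <- zc[starts[hit[1]]]
  }

  depth <- NA_real_
  if (!is.na(onset)) {
    post <- tv >= onset
    if (sum(post) >= 4)
      depth <- (max(d[post]) - min(d[post])) / (2 * mean(s[post]))
  }
  list(onset_fs = onset, frequency_ev = freq, depth = depth,
       half_period_fs = half_period,
       trace = data.frame(t = tv, signal = s, detrended = d))
}

fill_ends <- function(x) {
  ok <- which(!is.na(x))
  if (!length(ok)) return(rep(0, length(x)))
  x[seq_len(ok[1] - 1)] <- x[ok[1]]
  n <- length(x)
  last <- ok[length(ok)]
  if (last < n) x[(last + 1):n] <- x[last]
  x
}
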