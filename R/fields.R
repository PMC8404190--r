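#' Probe-field specifications
#'
#' `gaussian_pulse()` describes a single Gaussian XUV pulse by its
#' amplitude-envelope full width at half maximum (fs) and carrier energy
#' (eV); the envelope standard deviation is `fwhm / (2 sqrt(2 log 2))`.
#'
#' `apt_spec()` describes an attosecond pulse train: Gaussian bursts of
#' width `sigma_s` spaced by `t' = pi / omega_I` (half the driving-IR
#' period), each burst weighted by a Gaussian train envelope of width
#' `sigma_t` evaluated at its center, carrier `omega_X`.  Consecutive bursts carry a pi carrier-phase step
#' (`alternate_sign`), which places the spectral comb at odd harmonics of
#' the IR fundamental, spaced `2 omega_I`.  The IR field itself is assumed
#' filtered out and never enters the probe.  By default the carrier is the
#' 47th harmonic, `omega_X = harmonic_index * omega_I`, but it can be
#' overridden (the bundled figure presets pin it to 32.9 eV so that all
#' combs ionize into the same photoelectron window).
#'
#' @param fwhm amplitude-envelope full width at half maximum (fs).
#' @param omega_X carrier photon energy (eV).
#' @param amplitude peak field amplitude (arbitrary units).
#' @param t0 center time (fs).
#' @export
gaussian_pulse <- function(fwhm, omega_X, amplitude = 1, t0 = 0) {
  if (!is.finite(fwhm) || fwhm <= 0) stop("gaussian_pulse: fwhm must be > 0")
  if (!is.finite(omega_X) || omega_X <= 0) stop("gaussian_pulse: omega_X must be > 0")
  structure(list(fwhm = fwhm, sigma_t = fwhm / FWHM_SIGMA,
                 omega_X = omega_X, amplitude = amplitude, t0 = t0),
            class = c("gaussian_pulse", "probe_field"))
}

#' @rdname gaussian_pulse
#' @param omega_I IR fundamental photon energy (eV).
#' @param sigma_t train (envelope) width parameter (fs).
#' @param sigma_s single-burst width parameter (fs).
#' @param harmonic_index harmonic order setting the default carrier.
#' @param alternate_sign pi carrier-phase step between consecutive bursts.
#' @export
apt_spec <- function(omega_I, sigma_t, sigma_s,
                     omega_X = harmonic_index * omega_I,
                     harmonic_index = 47L, amplitude = 1, t0 = 0,
                     alternate_sign = TRUE) {
  if (!is.finite(omega_I) || omega_I <= 0) stop("apt_spec: omega_I must be > 0")
  t_prime <- au_to_fs(pi / ev_to_au(omega_I))
  if (sigma_s >= t_prime)
    stop("apt_spec: bursts overlap (sigma_s >= t' = pi/omega_I)")
  if (sigma_t <= sigma_s)
    stop("apt_spec: train envelope must be wider than a single burst")
  structure(list(omega_I = omega_I, sigma_t = sigma_t, sigma_s = sigma_s,
                 omega_X = omega_X, harmonic_index = harmonic_index,
                 amplitude = amplitude, t0 = t0,
                 alternate_sign = alternate_sign, t_prime = t_prime),
            class = c("apt_spec", "probe_field"))
}

#' @export
print.gaussian_pulse <- function(x, ...) {
  cat(sprintf("<gaussian_pulse> fwhm %.4g fs, carrier %.4g eV\n", x$fwhm, x$omega_X))
  invisible(x)
}

#' @export
print.apt_spec <- function(x, ...) {
  cat(sprintf("<apt_spec> omega_I %.3g eV (t' = %.4g fs), sigma_t %.3g fs, sigma_s %.3g fs, carrier %.4g eV\n",
              x$omega_I, x$t_prime, x$sigma_t, x$sigma_s, x$omega_X))
  invisible(x)
}

#' Complex field envelope in the rotating frame
#'
#' The probe enters the perturbative ionization signal only through its
#' envelope in the frame rotating at the carrier `omega_X`: a real
#' Gaussian for a single pulse; for a pulse train, the Gaussian train
#' envelope times the sign-alternating burst comb.  Evaluated in closed
#' form (bursts truncated where the train envelope is below 1e-8).
#'
#' @param probe a [gaussian_pulse()] or [apt_spec()].
#' @param t times (fs).
#' @return complex vector, same length as `t`.
#' @export
field_envelope <- function(probe, t) UseMethod("field_envelope")

#' @export
field_envelope.gaussian_pulse <- function(probe, t) {
  probe$amplitude * exp(-(t - probe$t0)^2 / (2 * probe$sigma_t^2)) + 0i
}

#' @export
field_envelope.apt_spec <- function(probe, t) {
  tp <- probe$t_prime
  kmax <- ceiling(probe$sigma_t * sqrt(2 * log(1e8)) / tp)
  tt <- t - probe$t0
  comb <- 0
  for (k in -kmax:kmax) {
    s <- if (probe$alternate_sign) (-1)^k else 1
    w <- exp(-(k * tp)^2 / (2 * probe$sigma_t^2))
    comb <- comb + s * w * exp(-(tt - k * tp)^2 / (2 * probe$sigma_s^2))
  }
  probe$amplitude * comb + 0i
}

#' Sample a probe field on a time axis
#'
#' Returns the analytic-signal samples `envelope(t) * exp(-i omega_X t)`
#' on a uniform time axis.  `sample_gaussian` warns when the window
#' truncates the envelope above 1e-6 of its peak; `sample_apt` requires
#' the sampling to resolve the bursts (at least 16 samples per burst
#' fwhm).
#'
#' @param pulse a [gaussian_pulse()].
#' @param spec an [apt_spec()].
#' @param times uniform time axis (fs).
#' @return Object of class `sampled_field`: list with `times`, complex
#'   `values`, and `omega_X` (eV).
#' @export
sample_gaussian <- function(pulse, times) {
  check_uniform(times, "sample_gaussian")
  env <- field_envelope(pulse, times)
  if (max(Mod(env[c(1, length(env))])) > 1e-6 * max(Mod(env), 1e-300))
    warning("sample_gaussian: time window truncates the envelope above 1e-6 of peak")
  sampled_field(times, env * carrier(pulse, times), pulse$omega_X)
}

#' @rdname sample_gaussian
#' @export
sample_apt <- function(spec, times) {
  check_uniform(times, "sample_apt")
  dt <- times[2] - times[1]
  burst_fwhm <- FWHM_SIGMA * spec$sigma_s
  if (burst_fwhm / dt < 16)
    stop("sample_apt: sampling too coarse (need >= 16 samples per burst fwhm)")
  env <- field_envelope(spec, times)
  sampled_field(times, env * carrier(spec, times), spec$omega_X)
}

carrier <- function(probe, t) exp(-1i * ev_to_au(probe$omega_X) * fs_to_au(t))

sampled_field <- function(times, values, omega_X) {
  structure(list(times = times, values = values, omega_X = omega_X),
            class = "sampled_field")
}

check_uniform <- function(times, where) {
  if (length(times) < 2) stop(where, ": need at least two samples")
  d <- diff(times)
  if (any(abs(d - d[1]) > 1e-9 * abs(d[1])) || d[1] <= 0)
    stop(where, ": time axis must be uniform and increasing")
  invisible(d[1])
}

#' Power spectrum of a sampled field
#'
#' Discrete Fourier transform of the analytic-signal samples; returns the
#' squared magnitude over a photon-energy axis (eV), normalized to unit
#' maximum.  Errors if spectral content at the Nyquist edge exceeds 1e-6
#' of the maximum (aliasing) and if the field is not negligible at the
#' window edges.
#'
#' @param field a `sampled_field`.
#' @return data.frame with columns `energy` (eV, ascending) and `power`.
#' @export
field_spectrum <- function(field) {
  v <- field$values
  n <- length(v)
  vmax <- max(Mod(v))
  if (vmax == 0) {
    e <- spectrum_axis(field)
    return(data.frame(energy = sort(e), power = rep(0, n)))
  }
  if (max(Mod(v[c(1, n)])) > 1e-6 * vmax)
    stop("field_spectrum: field not windowed to negligible edge amplitude")
  sp <- Mod(stats::fft(v))^2
  e <- spectrum_axis(field)
  if (field$omega_X > max(e))
    stop("field_spectrum: carrier beyond the representable band (aliasing); sample finer")
  # aliasing check: power near the frequency wrap-around of the axis
  wrap <- which.max(abs(diff(e)))
  if (max(sp[c(wrap, wrap + 1)]) > 1e-6 * max(sp))
    stop("field_spectrum: spectral content at Nyquist edge (aliasing)")
  o <- order(e)
  data.frame(energy = e[o], power = sp[o] / max(sp))
}

spectrum_axis <- function(field) {
  n <- length(field$times)
  dt <- fs_to_au(field$times[2] - field$times[1])
  i <- c(0:(ceiling(n / 2) - 1), -floor(n / 2):-1)
  # analytic signal exp(-i w t): bin j holds frequency +w at -2 pi j/(n dt)
  au_to_ev(-2 * pi * i / (n * dt))
}

#' Locate comb peaks in a power spectrum
#'
#' Local maxima above `threshold` times the global maximum, with sub-bin
#' positions by parabolic interpolation and fwhm by linear interpolation
#' of the half-maximum crossings.
#'
#' @param spectrum data.frame from [field_spectrum()].
#' @param threshold relative height cut (default 1e-3).
#' @return data.frame with columns `energy`, `height`, `fwhm` (possibly
#'   zero rows).
#' @export
comb_peaks <- function(spectrum, threshold = 1e-3) {
  e <- spectrum$energy; p <- spectrum$power
  n <- length(p)
  out <- list()
  cut <- threshold * max(p)
  for (i in seq(2, n - 1)) {
    if (p[i] >= cut && p[i] > p[i - 1] && p[i] >= p[i + 1]) {
      de <- e[2] - e[1]
      denom <- p[i - 1] - 2 * p[i] + p[i + 1]
      off <- if (denom < 0) 0.5 * (p[i - 1] - p[i + 1]) / denom else 0
      height <- p[i] - 0.25 * (p[i - 1] - p[i + 1]) * off
      half <- height / 2
      jl <- i; while (jl > 1 && p[jl] > half) jl <- jl - 1
      jr <- i; while (jr < n && p[jr] > half) jr <- jr + 1
      el <- if (p[jl] <= half && jl < i)
        e[jl] + (half - p[jl]) / (p[jl + 1] - p[jl]) * de else e[1]
      er <- if (p[jr] <= half && jr > i)
        e[jr - 1] + (p[jr - 1] - half) / (p[jr - 1] - p[jr]) * de else e[n]
      out[[length(out) + 1]] <- data.frame(energy = e[i] + off * de,
                                           height = height, fwhm = er - el)
    }
  }
  if (!length(out)) return(data.frame(energy = numeric(), height = numeric(),
                                      fwhm = numeric()))
  do.call(rbind, out)
}

#' Measure envelope widths from sampled envelopes
#'
#' For a Gaussian pulse: the full width at half maximum of the densely
#' sampled amplitude envelope (half-maximum crossings found by linear
#' interpolation).  For a pulse train: `burst` is the half-maximum width
#' of the central burst measured the same way, and `train` is recovered
#' from the burst-peak weights (a log-parabola through the three central
#' burst peaks, exact for a Gaussian train envelope).  All values in fs.
#'
#' @param probe a [gaussian_pulse()] or [apt_spec()].
#' @return For a pulse, a single number; for a train, `list(train, burst)`.
#' @export
envelope_fwhm <- function(probe) {
  if (inherits(probe, "gaussian_pulse")) {
    t <- seq(probe$t0 - 4 * probe$sigma_t, probe$t0 + 4 * probe$sigma_t,
             length.out = 4001)
    return(half_width(t, Mod(field_envelope(probe, t))))
  }
  tp <- probe$t_prime
  t <- seq(probe$t0 - tp / 2, probe$t0 + tp / 2, length.out = 4001)
  burst <- half_width(t, Mod(field_envelope(probe, t)))
  pk <- vapply(-1:1, function(k)
    max(Mod(field_envelope(probe, probe$t0 + k * tp +
                             seq(-3 * probe$sigma_s, 3 * probe$sigma_s,
                                 length.out = 801)))), 0)
  lp <- log(pk)
  curv <- lp[1] + lp[3] - 2 * lp[2]          # = -t'^2 / sigma_t^2
  train <- FWHM_SIGMA * tp / sqrt(-curv)
  list(train = train, burst = burst)
}

half_width <- function(t, v) {
  half <- max(v) / 2
  above <- v >= half
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  left <- if (i1 > 1)
    t[i1 - 1] + (half - v[i1 - 1]) / (v[i1] - v[i1 - 1]) * (t[i1] - t[i1 - 1])
  else t[1]
  right <- if (i2 < length(t))
    t[i2] + (v[i2] - half) / (v[i2] - v[i2 + 1]) * (t[i2 + 1] - t[i2])
  else t[length(t)]
  right - left
}

#' Default sampling axis for a probe field
#'
#' Uniform time axis covering the envelope to the 1e-8 level with sampling
#' fine enough for both the carrier (analytic signal) and the burst
#' structure.
#'
#' @param probe a probe field.
#' @param dt sample spacing (fs); default resolves the finest structure
#'   by a factor >= 16.
#' @export
field_times <- function(probe, dt = NULL) {
  span <- probe$sigma_t * sqrt(2 * log(1e8))
  finest <- if (inherits(probe, "apt_spec")) probe$sigma_s else probe$sigma_t
  if (is.null(dt)) {
    dt <- min(FWHM_SIGMA * finest / 24,
              au_to_fs(pi / ev_to_au(probe$omega_X)) / 4)
  }
  seq(probe$t0 - span, probe$t0 + span, by = dt)
}
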