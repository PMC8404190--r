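test_that("envelope widths reproduce the printed fwhm pairs", {
  expect_equal(envelope_fwhm(gaussian_pulse(0.71, 32.9)), 0.71, tolerance = 1e-3)
  expect_equal(envelope_fwhm(gaussian_pulse(5.29, 32.9)), 5.29, tolerance = 1e-3)
  w <- envelope_fwhm(apt_spec(0.5, 2.55, 0.25, omega_X = 32.9))
  expect_equal(w$train, 6.005, tolerance = 1e-2)   # sigma_t = 2.55 fs
  expect_equal(w$burst, 0.589, tolerance = 2e-3)   # sigma_s = 0.25 fs
})

test_that("burst spacing follows t' = pi / omega_I", {
  expect_equal(apt_spec(0.5, 2.55, 0.25)$t_prime, 4.1357, tolerance = 1e-4)
  expect_equal(apt_spec(0.7, 2.55, 0.25)$t_prime,
               pi / ev_to_au(0.7) * AUT_FS, tolerance = 1e-12)
})

test_that("probe constructors enforce their invariants", {
  expect_error(gaussian_pulse(-1, 32.9), "fwhm")
  expect_error(apt_spec(0.5, 2.55, 5), "overlap")       # sigma_s >= t'
  expect_error(apt_spec(0.5, 0.2, 0.25), "wider")       # sigma_t <= sigma_s
  expect_error(sample_apt(apt_spec(0.5, 2.55, 0.25),
                          seq(-20, 20, by = 0.1)), "16 samples")
  expect_warning(sample_gaussian(gaussian_pulse(5, 30), seq(-3, 3, by = 0.01)),
                 "truncates")
})

test_that("spectra recover carriers, widths and the harmonic comb", {
  # zero amplitude -> identically zero field
  p0 <- gaussian_pulse(1, 30, amplitude = 0)
  expect_true(all(sample_gaussian(p0, field_times(p0))$values == 0))

  # single pulse: one spectral peak at the carrier
  p <- gaussian_pulse(5.29, 32.9)
  sp <- field_spectrum(sample_gaussian(p, field_times(p)))
  pk <- comb_peaks(sp)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$energy, 32.9, tolerance = 1e-3)
  # spectral intensity fwhm: 2 sqrt(ln 2) / sigma for sigma = fwhm/2.3548
  # (in energy units: 0.4879 eV for the 5.29 fs pulse)
  expect_equal(pk$fwhm,
               2 * sqrt(log(2)) / fs_to_au(5.29 / FWHM_SIGMA) * HARTREE_EV,
               tolerance = 0.02)

  # comb: adjacent teeth separated by 2 omega_I for all presets
  for (wI in c(0.5, 0.6, 0.7)) {
    a <- apt_spec(wI, 2.55, 0.25, omega_X = 32.9)
    f <- sample_apt(a, field_times(a))
    spa <- field_spectrum(f)
    bin <- spa$energy[2] - spa$energy[1]
    pka <- comb_peaks(spa, threshold = 0.05)
    expect_gt(nrow(pka), 3)
    expect_lt(max(abs(diff(sort(pka$energy)) - 2 * wI)), bin)
  }

  # symmetric envelope -> tooth heights symmetric about the center
  a <- apt_spec(0.5, 2.55, 0.25)  # omega_X = 47 * 0.5 = 23.5, tooth ON carrier
  pka <- comb_peaks(field_spectrum(sample_apt(a, field_times(a))), 1e-3)
  hs <- pka$height[order(pka$energy)]
  expect_lt(max(abs(hs - rev(hs))), 1e-6)

  # single-burst limit: sigma_t << t' leaves one broad Gaussian
  sap <- apt_spec(0.5, 0.3, 0.25, omega_X = 32.9)
  pks <- comb_peaks(field_spectrum(sample_apt(sap, field_times(sap))),
                    threshold = 0.05)
  expect_identical(nrow(pks), 1L)

  # tooth width shrinks monotonically as the train envelope grows
  widths <- vapply(c(2, 4, 8), function(st) {
    a <- apt_spec(0.5, st, 0.25, omega_X = 32.9)
    pk <- comb_peaks(field_spectrum(sample_apt(a, field_times(a))), 0.5)
    pk$fwhm[which.min(abs(pk$energy - 32.4))]
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("comb equals the analytic burst-spectrum x envelope-comb oracle", {
  a <- apt_spec(0.5, 2.55, 0.25, omega_X = 32.9)
  tt <- field_times(a)
  f <- sample_apt(a, tt)
  n <- length(tt)
  dt <- fs_to_au(tt[2] - tt[1])
  # oracle: continuous-time Fourier transform of the closed-form train,
  # evaluated by direct summation at selected energies
  tp <- fs_to_au(a$t_prime)
  ss <- fs_to_au(a$sigma_s); st <- fs_to_au(a$sigma_t)
  kmax <- ceiling(a$sigma_t * sqrt(2 * log(1e8)) / a$t_prime)
  oracle <- function(w_ev) {
    w <- ev_to_au(w_ev - a$omega_X)
    burst <- sqrt(2 * pi) * ss * exp(-ss^2 * w^2 / 2)
    comb <- sum(vapply(-kmax:kmax, function(k)
      (-1)^k * exp(-(k * tp)^2 / (2 * st^2)) * cos(w * k * tp), 0))
    burst * comb
  }
  dft <- function(w_ev) {
    w <- ev_to_au(w_ev)
    ph <- exp(1i * w * fs_to_au(tt))
    sum(f$values * ph) * dt
  }
  for (w_ev in c(32.4, 33.4, 32.9, 31.4, 33.0)) {
    expect_equal(Mod(dft(w_ev)), abs(oracle(w_ev)), tolerance = 1e-6)
  }
})

test_that("Parseval holds between time samples and the DFT", {
  a <- apt_spec(0.6, 2.55, 0.25, omega_X = 32.9)
  f <- sample_apt(a, field_times(a))
  n <- length(f$values)
  et <- sum(Mod(f$values)^2)
  ew <- sum(Mod(stats::fft(f$values))^2) / n
  expect_equal(et, ew, tolerance = 1e-10)
})

test_that("aliasing and edge truncation are detected", {
  p <- gaussian_pulse(2, 32.9)
  tt <- seq(-8, 8, by = 0.2)  # carrier far beyond the representable band
  env <- field_envelope(p, tt)
  f <- structure(list(times = tt,
                      values = env * exp(-1i * ev_to_au(p$omega_X) * fs_to_au(tt)),
                      omega_X = p$omega_X),
                 class = "sampled_field")
  expect_error(field_spectrum(f), "alias")
})
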