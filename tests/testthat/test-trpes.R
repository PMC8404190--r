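test_that("signal vanishes for zero field and scales as |E|^2", {
  ft <- flat_twolevel()
  traj <- source_trajectory(ft$model, ft$wp, t_final_fs = 8)
  p0 <- gaussian_pulse(1.5, 26, amplitude = 0, t0 = 0)
  expect_equal(ionization_amplitude(ft$model, traj, p0, T = 4, omega_p = 6), 0)

  p1 <- gaussian_pulse(1.5, 26, amplitude = 1)
  p3 <- gaussian_pulse(1.5, 26, amplitude = 3)
  s1 <- ionization_amplitude(ft$model, traj, p1, T = 4, omega_p = 6)
  s3 <- ionization_amplitude(ft$model, traj, p3, T = 4, omega_p = 6)
  expect_gt(s1, 0)
  expect_equal(s3 / s1, 9, tolerance = 1e-10)
})

test_that("static level structure puts the peak at omega_X - IP", {
  # stationary valence amplitude, flat surfaces, IP = 20 eV from V0;
  # a long probe at 26 eV must maximize the signal at omega_p = 6 eV
  ft <- flat_twolevel(weights = c(1, 0))
  traj <- source_trajectory(ft$model, ft$wp, t_final_fs = 30)
  probe <- gaussian_pulse(8, 26, t0 = 0)
  sg <- signal_grid(c(15, 15.5), seq(5, 7, by = 0.1))
  sp <- spectrogram(ft$model, traj, probe, sg)
  pk <- band_peaks(sp, T = 15)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$energy, 6, tolerance = 0.05)
})

test_that("Gram-band spectrogram agrees with the direct driven route", {
  m <- small_coupled_model(masses = c(500, 500))
  wp <- small_packet(m, p1 = 1, mix = 0.5)
  traj <- source_trajectory(m, wp, t_final_fs = 25)
  probe <- gaussian_pulse(2, 30)
  sg <- signal_grid(seq(10, 14, by = 1), seq(1, 5, by = 0.5))
  sp <- spectrogram(m, traj, probe, sg, normalize = FALSE)
  D <- outer(seq_along(sp$delays), seq_along(sp$energies),
             Vectorize(function(it, ie)
               ionization_amplitude(m, traj, probe, T = sp$delays[it],
                                    omega_p = sp$energies[ie])))
  # the routes truncate differently (Gram: pair lag <= 6 sigma_t; direct:
  # samples within 4 sigma_t of the delay), so pointwise agreement is
  # limited by the e^-8 envelope tails relative to the signal scale
  expect_lt(max(abs(sp$S - D)) / max(sp$S), 1e-3)
})

test_that("both routes agree with a dense ion-surface oracle", {
  ft <- flat_twolevel(n1 = 16, n2 = 8)
  m <- ft$model
  traj <- source_trajectory(m, ft$wp, t_final_fs = 12)
  probe <- gaussian_pulse(1.2, 25)
  Tdel <- 6; wp_ev <- 5.2
  ref <- au_to_ev(min(m$I1))
  dt_au <- fs_to_au(traj$src_dt)
  U <- dense_ion_propagator(m, ref, dt_au)
  st <- traj$src_times
  wts <- field_envelope(probe, st - Tdel) *
    exp(1i * ev_to_au(wp_ev - probe$omega_X + ref) * fs_to_au(st))
  acc <- rep(0i, nrow(traj$source))
  for (k in seq_along(st)) {
    acc <- U %*% acc
    acc <- acc - 1i * dt_au * wts[k] * traj$source[, k]
  }
  oracle <- sum(Mod(acc)^2) * m$grid$d1 * m$grid$d2
  direct <- ionization_amplitude(m, traj, probe, T = Tdel, omega_p = wp_ev)
  # dense exponential vs Strang step: physics agreement, not bitwise
  expect_equal(direct, oracle, tolerance = 2e-3)
})

test_that("resonant comb spacing is required for delay-domain interference", {
  # two stationary, non-interacting flat components: an APT whose tooth
  # spacing (1 eV) matches the gap beats strongly in the overlapped band;
  # with the gap detuned to the comb midpoint (1.5 eV) the beat is gone.
  # A long train envelope keeps the teeth narrow (0.08 eV) so the
  # detuned tooth tails do not touch.
  probe <- apt_spec(0.5, 6, 0.25, omega_X = 26)
  depth_for <- function(delta_ev) {
    ft <- flat_twolevel(delta_ev = delta_ev, ip_ev = 20)
    traj <- source_trajectory(ft$model, ft$wp, t_final_fs = 66)
    # measure at the 6.5 eV tooth: resonant (gap = tooth spacing) there,
    # detuned gap 1.5 eV puts the other state's comb at the midpoints
    # (whose faint tail-tail interference lives *between* the teeth)
    sg <- signal_grid(seq(30, 40, by = 0.25), seq(6.4, 6.6, by = 0.1))
    sp <- spectrogram(ft$model, traj, probe, sg, normalize = FALSE)
    s <- rowSums(sp$S)
    (max(s) - min(s)) / (max(s) + min(s))
  }
  d_res <- depth_for(1)
  d_det <- depth_for(1.5)
  expect_lt(d_det, 0.01)
  expect_gt(d_res, 10 * d_det)
})

test_that("spectrograms are deterministic and normalized", {
  ft <- flat_twolevel()
  traj <- source_trajectory(ft$model, ft$wp, t_final_fs = 10)
  probe <- gaussian_pulse(1.5, 26)
  sg <- signal_grid(c(4, 5), seq(5, 7, by = 0.25))
  a <- spectrogram(ft$model, traj, probe, sg)
  b <- spectrogram(ft$model, traj, probe, sg)
  expect_identical(a$S, b$S)
  expect_equal(max(a$S), 1)
  expect_true(all(a$S >= 0))
  expect_error(spectrogram(ft$model, traj, probe,
                           signal_grid(c(9, 10), seq(5, 7, by = 0.5))),
               "cover")
})
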