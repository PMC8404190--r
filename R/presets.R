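#' Frozen parameters of the calibrated demonstration model
#'
#' The two-mode vibronic model used throughout the examples and the
#' acceptance checks: a bound Morse ground state, a dissociative excited
#' state crossed diabatically along the reaction coordinate, a linear
#' coupling in the perpendicular mode gated around the crossing, and an
#' ionized surface roughly parallel to the excited state placing the
#' photoelectron bands of a 32.9 eV probe in a 3-9 eV window.  The
#' numbers were fixed once within the near-degenerate family identified
#' by [calibrate_paper_model()] (diabatic population transfer starting
#' near 5 fs after impulsive excitation, asymptotic adiabatic gap near
#' 1 eV, band branching resolved between 10 and 15 fs); the residual
#' freedom was resolved by the sideband-interference onset behaviour,
#' which is too expensive for the search loop (see the methods
#' vignette).  They are committed here so that runs are fast and
#' deterministic.
#'
#' @keywords internal
paper_model_params <- function() {
  list(
    grid = list(n1 = 256L, n2 = 32L,
                r1_lim = c(-4.0, 26.0), r2_lim = c(-2.0, 2.0),
                masses = c(1836, 1836)),
    v0 = list(d0_ev = 1.50, a0 = 0.45, r1_0 = 0.0),
    v1 = list(b1_ev = 2.50, beta1 = 1.30, c1_ev = 0.50),
    w = list(lambda_ev = 0.50, r_c = 2.28, s_c = 0.60, r2_w = -0.50),
    ion = list(bi_ev = 2.50, beta_i = 1.30, ci_ev = 26.90),
    omega2_ev = 0.10,
    mu = 1.0
  )
}

#' Bundled experiment presets
#'
#' Returns a complete, validated configuration bundle for a named
#' experiment:
#' \describe{
#'   \item{`paper_model`}{the calibrated conical-intersection model, no
#'     probes: the common substrate of the figure presets.}
#'   \item{`fig3`}{single Gaussian probes of 0.71 fs and 5.29 fs fwhm at
#'     32.9 eV -- the time-resolution/energy-resolution dichotomy.}
#'   \item{`fig4_05`, `fig4_06`, `fig4_07`}{attosecond pulse trains with
#'     IR fundamentals 0.5, 0.6, 0.7 eV, train width `sigma_t` = 2.55 fs
#'     (6 fs fwhm) and burst width `sigma_s` = 0.25 fs (0.59 fs fwhm),
#'     carrier pinned at 32.9 eV.}
#'   \item{`toy_harmonic`}{uncoupled 2D harmonic ground surface with
#'     closed-form zero-point energy -- propagation fixtures.}
#'   \item{`toy_twolevel`}{flat surfaces, 1 eV gap, no coupling -- the
#'     analytic two-level photoionization fixture.}
#' }
#'
#' @param name preset name.
#' @return A list of class `preset_bundle` with elements `name`, `model`
#'   (parameter list for [build_model()] or a field recipe for the toys),
#'   `probes` (list of probe specs), `signal` (delay/energy axes), and
#'   `propagation` (time step, duration, strides).
#' @export
make_preset <- function(name) {
  sig_default <- list(delays = seq(0, 35, by = 0.5),
                      energies = seq(3, 9, by = 0.1))
  prop_default <- list(dt_fs = 0.1 * AUT_FS, t_final_fs = 45.3,
                       snapshot_stride = 80L, source_stride = 15L)
  bundle <- switch(
    name,
    paper_model = list(model = paper_model_params(), probes = list()),
    fig3 = list(model = paper_model_params(),
                probes = list(short = gaussian_pulse(0.71, 32.9),
                              long = gaussian_pulse(5.29, 32.9))),
    fig4_05 = list(model = paper_model_params(),
                   probes = list(apt = apt_spec(0.5, 2.55, 0.25, omega_X = 32.9))),
    fig4_06 = list(model = paper_model_params(),
                   probes = list(apt = apt_spec(0.6, 2.55, 0.25, omega_X = 32.9))),
    fig4_07 = list(model = paper_model_params(),
                   probes = list(apt = apt_spec(0.7, 2.55, 0.25, omega_X = 32.9))),
    toy_harmonic = list(model = list(toy = "harmonic", omega_ev = 0.5,
                                     gap_ev = 2, ip_ev = 10,
                                     n1 = 64L, n2 = 64L, half_span = 4,
                                     masses = c(100, 100)),
                        probes = list()),
    toy_twolevel = list(model = list(toy = "twolevel", gap_ev = 1, ip_ev = 20,
                                     n1 = 16L, n2 = 8L, half_span = 8,
                                     masses = c(1836, 1836)),
                        probes = list()),
    stop("make_preset: unknown preset '", name, "'")
  )
  bundle$name <- name
  bundle$signal <- sig_default
  bundle$propagation <- prop_default
  class(bundle) <- "preset_bundle"
  bundle
}

#' Build the model of a preset bundle
#'
#' @param bundle a [make_preset()] bundle.
#' @export
preset_model <- function(bundle) {
  p <- bundle$model
  if (is.null(p$toy)) return(build_model(p))
  g <- grid2d(p$n1, p$n2, c(-p$half_span, p$half_span),
              c(-p$half_span, p$half_span), p$masses)
  R1 <- matrix(g$r1, g$n1, g$n2)
  R2 <- matrix(g$r2, g$n1, g$n2, byrow = TRUE)
  zero <- matrix(0, g$n1, g$n2)
  if (p$toy == "harmonic") {
    w <- ev_to_au(p$omega_ev)
    V0 <- 0.5 * g$masses[1] * w^2 * R1^2 + 0.5 * g$masses[2] * w^2 * R2^2
    V1 <- V0 + ev_to_au(p$gap_ev)
  } else {
    V0 <- zero
    V1 <- zero + ev_to_au(p$gap_ev)
  }
  I1 <- V1 + ev_to_au(p$ip_ev)
  model_from_fields(g, V0, V1, zero, I1, mu = 1, validate = FALSE)
}

#' Calibrate the demonstration model against its target observables
#'
#' Deterministic coarse grid search (no randomness) over the excited-state
#' slope `beta1`, the coupling center `r_c`, the coupling strength
#' `lambda`, and the asymptotic diabatic offset `c1_ev`, minimizing the
#' squared mismatch of three observables of a short propagation:
#' \itemize{
#'   \item arrival: time at which the diabatic ground-state population
#'     first exceeds 1\% (target `t_arrival_fs`, 5 fs);
#'   \item gap: adiabatic gap at the outer edge of the reaction coordinate
#'     (target `gap_ev`, 1 eV);
#'   \item branching: time at which the gap evaluated at the mean packet
#'     position reaches half its asymptotic value (target
#'     `t_branch_fs`, 12.5 fs) -- a cheap proxy for the delay at which the
#'     photoelectron bands become resolvable.
#' }
#' The committed [paper_model_params()] were produced by this routine; the
#' exported function exists so that the calibration is reproducible and
#' testable at small search budgets.
#'
#' @param beta1,r_c,lambda,c1_ev candidate values for each searched
#'   parameter (vectors; the Cartesian product is scanned in order).
#' @param base parameter list to vary (default [paper_model_params()]).
#' @param targets list with `t_arrival_fs`, `gap_ev`, `t_branch_fs`.
#' @param weights squared-error weights for the three observables.
#' @param t_final_fs propagation length per candidate.
#' @param dt_fs propagation step per candidate (coarser than production).
#' @return List with `params` (best parameter list), `score`, and
#'   `report` (data.frame of all candidates and their observables).
#' @export
calibrate_paper_model <- function(beta1, r_c, lambda, c1_ev,
                                  base = paper_model_params(),
                                  targets = list(t_arrival_fs = 5,
                                                 gap_ev = 1,
                                                 t_branch_fs = 12.5),
                                  weights = c(1, 4, 0.25),
                                  t_final_fs = 20, dt_fs = 0.5 * AUT_FS) {
  cand <- expand.grid(beta1 = beta1, r_c = r_c, lambda = lambda,
                      c1_ev = c1_ev, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cand))
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    p <- base
    p$v1$beta1 <- cand$beta1[i]
    p$w$r_c <- cand$r_c[i]
    p$w$lambda_ev <- cand$lambda[i]
    p$v1$c1_ev <- cand$c1_ev[i]
    obs <- tryCatch(calibration_observables(p, t_final_fs, dt_fs),
                    error = function(e) NULL)
    if (is.null(obs)) {
      rows[[i]] <- cbind(cand[i, ], t_arrival = NA, gap_edge = NA,
                        t_branch = NA, score = Inf)
      next
    }
    err <- c(obs$t_arrival - targets$t_arrival_fs,
             obs$gap_edge - targets$gap_ev,
             obs$t_branch - targets$t_branch_fs)
    err[is.na(err)] <- 1e3
    score <- sum(weights * err^2)
    rows[[i]] <- cbind(cand[i, ], t_arrival = obs$t_arrival,
                       gap_edge = obs$gap_edge, t_branch = obs$t_branch,
                       score = score)
    if (is.null(best) || score < best$score)
      best <- list(params = p, score = score, obs = obs)
  }
  if (is.null(best))
    stop("calibrate_paper_model: no candidate produced a valid model")
  report <- do.call(rbind, rows)
  best$report <- report
  best
}

calibration_observables <- function(params, t_final_fs, dt_fs) {
  model <- build_model(params)
  ad <- adiabatic_transform(model)
  j0 <- which.min(abs(model$grid$r2))
  gap_edge <- au_to_ev(ad$gap[model$grid$n1 - 1, j0])
  wp <- relax_ground_state(model, tol = 1e-9)
  wp <- vertical_excite(wp)
  n_steps <- ceiling(t_final_fs / dt_fs)
  traj <- propagate(model, wp, dt = dt_fs, n_steps = n_steps,
                    snapshot_stride = max(1L, round(0.25 / dt_fs)))
  # arrival: absolute 1% of the total norm, not relative to the max
  cross <- which(traj$pops$P0 > 0.01)
  t_arrival <- if (length(cross)) {
    i <- cross[1]
    if (i == 1) traj$pops$t[1] else
      traj$pops$t[i - 1] + (0.01 - traj$pops$P0[i - 1]) /
        (traj$pops$P0[i] - traj$pops$P0[i - 1]) * dt_fs
  } else NA_real_
  # branching proxy: gap at the mean position of the excited-state packet
  gap_line <- au_to_ev(ad$gap[, j0])
  ns <- length(traj$snap_times)
  gap_at <- numeric(ns)
  for (i in seq_len(ns)) {
    dens <- rowSums(abs(traj$snap1[, , i])^2)
    gap_at[i] <- sum(gap_line * dens) / sum(dens)
  }
  # branching time: gap at the packet recovers to half its asymptotic
  # value *after* the CI passage (the pre-crossing gap is large too)
  imin <- which.min(gap_at)
  half <- which(seq_along(gap_at) > imin & gap_at >= gap_edge / 2)
  t_branch <- if (length(half)) traj$snap_times[half[1]] else NA_real_
  list(t_arrival = t_arrival, gap_edge = gap_edge, t_branch = t_branch)
}
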