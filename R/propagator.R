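#' Two-component nuclear wave packet
#'
#' Amplitudes on the diabatic surfaces `V0` and `V1`, on the model grid,
#' with a time stamp in fs.
#'
#' @param psi0,psi1 complex `n1 x n2` matrices (amplitude on `V0`, `V1`).
#' @param grid the [grid2d()] the amplitudes live on.
#' @param t time stamp (fs).
#' @export
wavepacket <- function(psi0, psi1, grid, t = 0) {
  stopifnot(inherits(grid, "grid2d"))
  dims <- c(grid$n1, grid$n2)
  if (!all(dim(psi0) == dims) || !all(dim(psi1) == dims))
    stop("wavepacket: component dimensions do not match the grid")
  structure(list(psi0 = psi0 + 0i, psi1 = psi1 + 0i, grid = grid, t = t),
            class = "wavepacket")
}

#' @export
print.wavepacket <- function(x, ...) {
  cat(sprintf("<wavepacket> t = %.4g fs, P(V0) = %.6f, P(V1) = %.6f\n",
              x$t, wp_population(x, 0), wp_population(x, 1)))
  invisible(x)
}

#' Norms and expectation values of a wave packet
#'
#' `wp_norm` returns the total squared norm, `wp_population` the squared
#' norm of one diabatic component, `wp_expect` the mean position
#' `c(R1, R2)` (bohr) over both components.
#'
#' @param wp a [wavepacket()].
#' @param component 0 or 1 (diabatic surface index).
#' @export
wp_norm <- function(wp) {
  dV <- wp$grid$d1 * wp$grid$d2
  (sum(abs(wp$psi0)^2) + sum(abs(wp$psi1)^2)) * dV
}

#' @rdname wp_norm
#' @export
wp_population <- function(wp, component) {
  dV <- wp$grid$d1 * wp$grid$d2
  psi <- if (component == 0) wp$psi0 else wp$psi1
  sum(abs(psi)^2) * dV
}

#' @rdname wp_norm
#' @export
wp_expect <- function(wp) {
  g <- wp$grid
  dens <- abs(wp$psi0)^2 + abs(wp$psi1)^2
  w <- sum(dens)
  c(R1 = sum(rowSums(dens) * g$r1) / w, R2 = sum(colSums(dens) * g$r2) / w)
}

#' Impulsive (vertical) excitation
#'
#' Moves the full amplitude from the `V0` component to the `V1` component,
#' unchanged: the delta-pulse limit of the actinic pump, which launches
#' the dynamics on the dissociative excited state without distorting the
#' nuclear density.
#'
#' @param wp a [wavepacket()] residing entirely on `V0`.
#' @return The excited [wavepacket()].
#' @export
vertical_excite <- function(wp) {
  if (wp_population(wp, 1) > 1e-12 * max(wp_norm(wp), 1e-300))
    stop("vertical_excite: packet is not entirely on V0")
  wavepacket(matrix(0i, wp$grid$n1, wp$grid$n2), wp$psi0, wp$grid, t = wp$t)
}

#' Complex absorbing potential at the dissociative grid edge
#'
#' Cubic absorbing potential switched on over the outer `fraction` of the
#' `R1` range (the dissociative edge).  The bound `R2` mode needs none.
#'
#' @param grid a [grid2d()].
#' @param fraction fraction of the `R1` range covered by the absorber.
#' @param strength_ev absorber height at the last grid point (eV).
#' @return `n1 x n2` matrix (hartree) to pass as `cap`.
#' @export
make_cap <- function(grid, fraction = 0.15, strength_ev = 3) {
  r1 <- grid$r1
  r_hi <- r1[length(r1)] + grid$d1
  r_start <- r_hi - fraction * (r_hi - r1[1])
  x <- pmax(0, (r1 - r_start) / (r_hi - r_start))
  matrix(ev_to_au(strength_ev) * x^3, grid$n1, grid$n2)
}

#' Single split-operator step
#'
#' One Strang step of duration `dt` (fs): half kinetic (FFT per
#' component), full coupled-potential step (closed-form 2x2 matrix
#' exponential), half kinetic, then the absorbing mask.  `dt = 0` is the
#' identity.  The splitting is unconditionally stable (unitary before the
#' mask); accuracy is second order in `dt`.
#'
#' @param model a `diabatic_model`.
#' @param wp a [wavepacket()].
#' @param dt time step (fs).
#' @param cap absorbing-potential matrix (hartree), e.g. [make_cap()];
#'   zero matrix for none.
#' @export
step_wavepacket <- function(model, wp, dt, cap = NULL) {
  g <- model$grid
  if (is.null(cap)) cap <- matrix(0, g$n1, g$n2)
  norm_in <- wp_norm(wp)
  res <- cpp_step(model$V0, model$V1, model$W, cap, wp$psi0, wp$psi1,
                  g$masses[1], g$masses[2], g$k1, g$k2, fs_to_au(dt))
  out <- wavepacket(res$psi0, res$psi1, g, t = wp$t + dt)
  if (wp_norm(out) > norm_in * (1 + 1e-8))
    stop("step_wavepacket: norm growth beyond 1e-8 in one step (numerical instability)")
  out
}

#' Propagate the coupled-surface wave packet
#'
#' Repeated Strang steps with per-step population accounting, wave-packet
#' snapshots every `snapshot_stride` steps, and (optionally) the
#' ionization source `mu * (psi0 + psi1)` every `source_stride` steps --
#' the quantity the photoelectron signal is built from.
#'
#' @param model a `diabatic_model`.
#' @param wp initial [wavepacket()].
#' @param dt time step (fs).  The default 0.1 atomic time units resolves
#'   the fastest potential phases of the bundled models by two orders of
#'   magnitude.
#' @param n_steps number of steps.
#' @param snapshot_stride steps between stored snapshots (default chosen
#'   to sample a 1 eV coherence period about 20 times).
#' @param collect_source store the ionization source field.
#' @param source_stride steps between source samples; the source spacing
#'   must resolve the attosecond burst envelope (about 16 samples per
#'   burst fwhm for the bundled pulse trains).
#' @param cap absorbing potential matrix (hartree); `NULL` (default) uses
#'   [make_cap()] on the model grid; pass a zero matrix to disable.
#' @return Object of class `trajectory`: snapshot arrays, per-step
#'   population traces, absorbed norm, and source samples.
#' @export
propagate <- function(model, wp, dt = 0.1 * AUT_FS, n_steps,
                      snapshot_stride = 80L, collect_source = FALSE,
                      source_stride = 15L, cap = NULL) {
  g <- model$grid
  if (is.null(cap)) cap <- make_cap(g)
  n_steps <- as.integer(n_steps)
  if (n_steps < 0) stop("propagate: n_steps must be >= 0")
  if (n_steps == 0) {
    return(structure(list(
      model = model, grid = g, dt = dt, t0 = wp$t,
      snap_times = wp$t, snap0 = array(wp$psi0, c(g$n1, g$n2, 1)),
      snap1 = array(wp$psi1, c(g$n1, g$n2, 1)),
      pops = data.frame(t = wp$t, P0 = wp_population(wp, 0),
                        P1 = wp_population(wp, 1), absorbed = 0),
      source = NULL, src_times = NULL, src_dt = NULL,
      final = wp), class = "trajectory"))
  }
  res <- cpp_propagate(model$V0, model$V1, model$W, cap,
                       wp$psi0, wp$psi1,
                       g$masses[1], g$masses[2], g$d1, g$d2, g$k1, g$k2,
                       fs_to_au(dt), n_steps,
                       as.integer(snapshot_stride), as.integer(source_stride),
                       model$mu, collect_source)
  t_step <- wp$t + dt * (0:n_steps)
  n_snap <- dim(res$snap0)[3]
  snap_times <- wp$t + dt * snapshot_stride * (0:(n_snap - 1))
  traj <- structure(list(
    model = model, grid = g, dt = dt, t0 = wp$t,
    snap_times = snap_times, snap0 = res$snap0, snap1 = res$snap1,
    pops = data.frame(t = t_step, P0 = res$pop0, P1 = res$pop1,
                      absorbed = res$absorbed),
    source = if (collect_source) res$source else NULL,
    src_times = if (collect_source)
      wp$t + dt * source_stride * (0:(ncol(res$source) - 1)) else NULL,
    src_dt = if (collect_source) dt * source_stride else NULL,
    final = wavepacket(res$psi0, res$psi1, g, t = wp$t + n_steps * dt)
  ), class = "trajectory")
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  tf <- x$final$t
  cat(sprintf("<trajectory> t in [%.3g, %.3g] fs, %d snapshots, absorbed %.3e",
              x$t0, tf, length(x$snap_times), utils::tail(x$pops$absorbed, 1)))
  cat(if (is.null(x$source)) "\n" else
    sprintf(", %d source samples (every %.4g fs)\n", ncol(x$source), x$src_dt))
  invisible(x)
}

#' Total energy expectation value
#'
#' `<H>` of a wave packet under the coupled diabatic Hamiltonian
#' (spectral kinetic energy plus the 2x2 potential), in hartree.  Used by
#' the conservation diagnostics.
#'
#' @param model a `diabatic_model`.
#' @param wp a [wavepacket()].
#' @export
wp_energy <- function(model, wp) {
  g <- wp$grid
  kin <- outer(g$k1^2 / (2 * g$masses[1]), rep(1, g$n2)) +
    outer(rep(1, g$n1), g$k2^2 / (2 * g$masses[2]))
  N <- g$n1 * g$n2
  dV <- g$d1 * g$d2
  tq <- 0
  for (psi in list(wp$psi0, wp$psi1)) {
    ph <- stats::fft(psi)
    tq <- tq + sum(kin * abs(ph)^2) * dV / N
  }
  vq <- sum(model$V0 * abs(wp$psi0)^2 + model$V1 * abs(wp$psi1)^2 +
              2 * Re(Conj(wp$psi0) * model$W * wp$psi1)) * dV
  tq + vq
}
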