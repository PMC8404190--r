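#' Two-dimensional coordinate grid
#'
#' Builds the uniform, FFT-periodic coordinate grid shared by all potential
#' fields and wave packets.  Coordinates are mass-weighted lengths in bohr;
#' `masses` are the effective masses (atomic units) conjugate to each
#' coordinate.  Point counts must be powers of two for the split-operator
#' FFTs.
#'
#' @param n1,n2 number of points along the reaction coordinate `R1` and the
#'   coupling coordinate `R2`; powers of two, at least 8.
#' @param r1_lim,r2_lim length-2 numeric, coordinate bounds (bohr).  The
#'   grid is periodic: points run from `min` to `max - d` with spacing
#'   `d = (max - min)/n`.
#' @param masses length-2 numeric, effective masses (atomic units).
#' @return An object of class `grid2d` with axis vectors `r1`, `r2`,
#'   spacings `d1`, `d2` and momentum axes `k1`, `k2`.
#' @export
grid2d <- function(n1, n2, r1_lim, r2_lim, masses) {
  is_pow2 <- function(n) n >= 8 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
  if (!is_pow2(n1) || !is_pow2(n2))
    stop("grid2d: n1 and n2 must be powers of two and >= 8")
  if (length(r1_lim) != 2 || length(r2_lim) != 2 ||
      diff(r1_lim) <= 0 || diff(r2_lim) <= 0)
    stop("grid2d: coordinate bounds must be strictly ordered length-2 vectors")
  if (length(masses) != 2 || any(!is.finite(masses)) || any(masses <= 0))
    stop("grid2d: masses must be two finite positive numbers")
  d1 <- diff(r1_lim) / n1
  d2 <- diff(r2_lim) / n2
  fftfreq <- function(n, d) {
    i <- c(0:(n / 2 - 1), -(n / 2):-1)
    2 * pi * i / (n * d)
  }
  structure(list(
    n1 = as.integer(n1), n2 = as.integer(n2),
    r1 = r1_lim[1] + (0:(n1 - 1)) * d1,
    r2 = r2_lim[1] + (0:(n2 - 1)) * d2,
    d1 = d1, d2 = d2,
    k1 = fftfreq(n1, d1), k2 = fftfreq(n2, d2),
    masses = as.numeric(masses)
  ), class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d, R1 in [%.3g, %.3g), R2 in [%.3g, %.3g) bohr, masses (%g, %g) a.u.\n",
              x$n1, x$n2, x$r1[1], x$r1[1] + x$n1 * x$d1,
              x$r2[1], x$r2[1] + x$n2 * x$d2, x$masses[1], x$masses[2]))
  invisible(x)
}

#' Assemble a diabatic model from explicit potential fields
#'
#' Low-level constructor used by [build_model()] and by test fixtures.
#' All fields are `n1 x n2` matrices in hartree on `grid`.
#'
#' @param grid a [grid2d()].
#' @param V0,V1 diabatic valence surfaces (hartree).
#' @param W diabatic coupling field (hartree).
#' @param I1 ionized-state surface (hartree).
#' @param mu constant ionization transition dipole (arbitrary units).
#' @param validate if `TRUE`, check the conical-intersection invariants
#'   (unique interior adiabatic-gap minimum, coupling vanishing at the
#'   `R1` edges).  Fixtures with flat or uncoupled surfaces set this to
#'   `FALSE`.
#' @return An object of class `diabatic_model`.
#' @export
model_from_fields <- function(grid, V0, V1, W, I1, mu = 1, validate = FALSE) {
  stopifnot(inherits(grid, "grid2d"))
  dims <- c(grid$n1, grid$n2)
  for (nm in c("V0", "V1", "W", "I1")) {
    f <- get(nm)
    if (!is.matrix(f) || !all(dim(f) == dims))
      stop(sprintf("model_from_fields: %s must be a %d x %d matrix", nm, dims[1], dims[2]))
    if (any(!is.finite(f)))
      stop(sprintf("model_from_fields: %s contains non-finite values", nm))
  }
  m <- structure(list(grid = grid, V0 = V0, V1 = V1, W = W, I1 = I1,
                      mu = mu, params = NULL),
                 class = "diabatic_model")
  if (validate) validate_model(m)
  m
}

validate_model <- function(model) {
  ad <- adiabatic_transform(model)
  idx <- which(ad$gap == min(ad$gap), arr.ind = TRUE)
  if (nrow(idx) != 1)
    stop("model validation: adiabatic gap minimum is not unique on the grid")
  n1 <- model$grid$n1; n2 <- model$grid$n2
  if (idx[1] <= 1 || idx[1] >= n1 || idx[2] <= 1 || idx[2] >= n2)
    stop("model validation: no interior adiabatic-gap minimum (conical intersection off-grid)")
  wmax <- max(abs(model$W))
  edge <- max(abs(model$W[c(1, n1), ]))
  if (wmax > 0 && edge > 1e-6 * wmax)
    stop("model validation: diabatic coupling does not vanish at the R1 grid edges")
  invisible(model)
}

#' Build the two-mode vibronic model
#'
#' Constructs the diabatic two-state model with a conical intersection:
#' a bound (Morse) diabatic ground state `V0`, a dissociative diabatic
#' excited state `V1` (repulsive exponential along `R1`), a linear
#' diabatic coupling `W` in the coupling coordinate `R2` gated by a
#' Gaussian window along `R1`, and the ionized surface `I1` roughly
#' parallel to `V1`.  In formulas (energies in hartree internally, the
#' parameter list is in eV/bohr):
#' \deqn{V_0 = D_0 (1 - e^{-a_0 (R_1 - R_1^0)})^2 + \tfrac12 m_2 \omega_2^2 R_2^2}
#' \deqn{V_1 = B_1 e^{-\beta_1 (R_1 - R_1^0)} + C_1 + \tfrac12 m_2 \omega_2^2 R_2^2}
#' \deqn{W = \lambda (R_2 - R_2^w) \exp(-(R_1 - R_c)^2 / 2 s_c^2)}
#' \deqn{I_1 = B_I e^{-\beta_I (R_1 - R_1^0)} + C_I + \tfrac12 m_2 \omega_2^2 R_2^2}
#' The adiabatic transformation of `V0, V1, W` exhibits a conical
#' intersection at `(R_1 = R_c, R_2 = R_2^w)` when `R_c` sits at the
#' diabatic crossing.  A nonzero seam offset `R_2^w` (key `r2_w`, default
#' 0) breaks the `R2` parity between the branched components; with the
#' seam exactly at the center of the Franck-Condon density the transferred
#' packet would carry odd coupling-mode symmetry and the electronic
#' coherence would vanish identically.
#'
#' @param params named list with entries `grid` (list `n1, n2, r1_lim,
#'   r2_lim, masses`), `v0` (list `d0_ev, a0, r1_0`), `v1` (list `b1_ev,
#'   beta1, c1_ev`), `w` (list `lambda_ev, r_c, s_c`), `ion` (list
#'   `bi_ev, beta_i, ci_ev`), `omega2_ev` (coupling-mode quantum), and
#'   optionally `mu` (default 1).  Energy parameters are eV, lengths bohr.
#' @param validate check conical-intersection invariants (default `TRUE`).
#' @return A `diabatic_model`.
#' @seealso [make_preset()] for the calibrated default parameter set.
#' @export
build_model <- function(params, validate = TRUE) {
  req <- c("grid", "v0", "v1", "w", "ion", "omega2_ev")
  miss <- setdiff(req, names(params))
  if (length(miss))
    stop("build_model: missing parameter sections: ", paste(miss, collapse = ", "))
  flat <- unlist(params[setdiff(req, "grid")])
  if (any(!is.finite(flat)))
    stop("build_model: non-finite model parameters: ",
         paste(names(flat)[!is.finite(flat)], collapse = ", "))
  g <- params$grid
  grid <- grid2d(g$n1, g$n2, g$r1_lim, g$r2_lim, g$masses)

  R1 <- matrix(grid$r1, grid$n1, grid$n2)
  R2 <- matrix(grid$r2, grid$n1, grid$n2, byrow = TRUE)
  ev <- function(x) x / HARTREE_EV
  w2 <- ev(params$omega2_ev)
  harm <- 0.5 * grid$masses[2] * w2^2 * R2^2

  p0 <- params$v0; p1 <- params$v1; pw <- params$w; pi1 <- params$ion
  V0 <- ev(p0$d0_ev) * (1 - exp(-p0$a0 * (R1 - p0$r1_0)))^2 + harm
  V1 <- ev(p1$b1_ev) * exp(-p1$beta1 * (R1 - p0$r1_0)) + ev(p1$c1_ev) + harm
  r2w <- if (is.null(pw$r2_w)) 0 else pw$r2_w
  W  <- ev(pw$lambda_ev) * (R2 - r2w) * exp(-(R1 - pw$r_c)^2 / (2 * pw$s_c^2))
  I1 <- ev(pi1$bi_ev) * exp(-pi1$beta_i * (R1 - p0$r1_0)) + ev(pi1$ci_ev) + harm

  m <- model_from_fields(grid, V0, V1, W, I1,
                         mu = if (is.null(params$mu)) 1 else params$mu,
                         validate = validate)
  m$params <- params
  m
}

#' Diabatic-to-adiabatic transformation
#'
#' Pointwise eigendecomposition of the 2x2 diabatic potential matrix
#' `[[V0, W], [W, V1]]`.  Returns the adiabatic surfaces, the gap, and the
#' mixing angle `theta` (branch `(-pi/4, pi/4]`, unwrapped along grid rows
#' for continuity; the angle is diagnostic only -- all dynamics run in the
#' diabatic basis).
#'
#' @param model a `diabatic_model`.
#' @return Object of class `adiabatic_view`: list with matrices `E_lower`,
#'   `E_upper`, `gap` (hartree) and `theta` (radians).
#' @export
adiabatic_transform <- function(model) {
  dV <- model$V1 - model$V0
  mean_ <- (model$V0 + model$V1) / 2
  r <- sqrt((dV / 2)^2 + model$W^2)
  theta <- 0.5 * atan2(2 * model$W, dV)
  # fold into (-pi/4, pi/4] and unwrap along rows (R1 direction)
  theta <- theta - (pi / 2) * round(theta / (pi / 2))
  for (j in seq_len(ncol(theta))) {
    th <- theta[, j]
    jump <- c(0, diff(th))
    th <- th - cumsum((pi / 2) * round(jump / (pi / 2)))
    theta[, j] <- th
  }
  structure(list(E_lower = mean_ - r, E_upper = mean_ + r,
                 gap = 2 * r, theta = theta, grid = model$grid),
            class = "adiabatic_view")
}

#' Relax to the ground vibrational state of the diabatic ground surface
#'
#' Imaginary-time split-operator propagation on `V0`, renormalizing each
#' step, until the energy change per step falls below `tol` hartree.  Used
#' to prepare the state that an impulsive actinic pump promotes to `V1`.
#'
#' @param model a `diabatic_model`.
#' @param dt_imag imaginary-time step (fs); the default (about 4 a.u.) is
#'   a robust compromise between filter selectivity and step count.
#' @param tol convergence threshold on the energy change per step (hartree).
#' @param max_steps step cap before a non-convergence error.
#' @return A [wavepacket()] with all amplitude on `V0` at `t = 0`, carrying
#'   the converged energy (hartree) in attribute `energy`.
#' @export
relax_ground_state <- function(model, dt_imag = 4 * AUT_FS, tol = 1e-10,
                               max_steps = 20000L) {
  g <- model$grid
  res <- cpp_relax(model$V0, g$masses[1], g$masses[2], g$d1, g$d2,
                   g$k1, g$k2, fs_to_au(dt_imag), tol, as.integer(max_steps))
  if (!res$converged)
    stop(sprintf("relax_ground_state: not converged after %d steps (dE = %.3e)",
                 max_steps, res$dE))
  wp <- wavepacket(res$psi, matrix(0i, g$n1, g$n2), g, t = 0)
  attr(wp, "energy") <- res$energy
  attr(wp, "iterations") <- res$iterations
  wp
}
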