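# Dense-matrix oracles, independent of the split-operator code path.
# The kinetic operator is built from explicit DFT matrices so that the
# oracle shares only the *definition* of the spectral Hamiltonian, not
# its implementation.

dense_hamiltonian <- function(model) {
  g <- model$grid
  n1 <- g$n1; n2 <- g$n2
  F1 <- stats::mvfft(diag(n1)); F2 <- stats::mvfft(diag(n2))
  K1 <- Conj(t(F1)) %*% diag(g$k1^2 / (2 * g$masses[1])) %*% F1 / n1
  K2 <- Conj(t(F2)) %*% diag(g$k2^2 / (2 * g$masses[2])) %*% F2 / n2
  Tm <- kronecker(diag(n2), K1) + kronecker(K2, diag(n1))
  H <- rbind(cbind(Tm + diag(as.vector(model$V0)), diag(as.vector(model$W))),
             cbind(diag(as.vector(model$W)), Tm + diag(as.vector(model$V1))))
  (H + Conj(t(H))) / 2
}

dense_propagator <- function(H, dt_au) {
  e <- eigen(H, symmetric = TRUE)
  e$vectors %*% (exp(-1i * dt_au * e$values) * Conj(t(e$vectors)))
}

# single-surface version (ionized-state propagation oracle)
dense_ion_propagator <- function(model, ref_ev, dt_au) {
  g <- model$grid
  n1 <- g$n1; n2 <- g$n2
  F1 <- stats::mvfft(diag(n1)); F2 <- stats::mvfft(diag(n2))
  K1 <- Conj(t(F1)) %*% diag(g$k1^2 / (2 * g$masses[1])) %*% F1 / n1
  K2 <- Conj(t(F2)) %*% diag(g$k2^2 / (2 * g$masses[2])) %*% F2 / n2
  Tm <- kronecker(diag(n2), K1) + kronecker(K2, diag(n1))
  H <- Tm + diag(as.vector(model$I1 - ev_to_au(ref_ev)))
  dense_propagator((H + Conj(t(H))) / 2, dt_au)
}

# small coupled fixture with an avoided crossing, light masses so that
# short propagations develop visible dynamics
small_coupled_model <- function(n = 16, masses = c(200, 200)) {
  g <- grid2d(n, n, c(-3, 3), c(-3, 3), masses)
  R1 <- matrix(g$r1, n, n); R2 <- matrix(g$r2, n, n, byrow = TRUE)
  model_from_fields(
    g,
    V0 = 0.05 * R1^2 + 0.05 * R2^2,
    V1 = 0.3 + 0.08 * (R1 - 0.5)^2 + 0.05 * R2^2,
    W = 0.15 * R2 * exp(-R1^2),
    I1 = 0.05 * R1^2 + 1)
}

small_packet <- function(model, p1 = 3, mix = 0.3) {
  g <- model$grid
  R1 <- matrix(g$r1, g$n1, g$n2); R2 <- matrix(g$r2, g$n1, g$n2, byrow = TRUE)
  psi <- exp(-((R1 - 0.4)^2 + R2^2) / (2 * 0.25^2)) * exp(1i * p1 * R1)
  wp <- wavepacket(psi, mix * psi, g)
  nrm <- sqrt(wp_norm(wp))
  wavepacket(psi / nrm, mix * psi / nrm, g)
}

no_cap <- function(model) matrix(0, model$grid$n1, model$grid$n2)

# flat two-level fixture: stationary uniform valence amplitude on both
# surfaces (gap delta_ev), same ion surface -- the analytically solvable
# photoionization testbed
flat_twolevel <- function(delta_ev = 1, ip_ev = 20, n1 = 16, n2 = 8,
                          weights = c(1, 1) / sqrt(2)) {
  g <- grid2d(n1, n2, c(-8, 8), c(-8, 8), c(1836, 1836))
  zero <- matrix(0, n1, n2)
  m <- model_from_fields(g, zero, zero + ev_to_au(delta_ev), zero,
                         zero + ev_to_au(ip_ev))
  amp <- 1 / sqrt(n1 * n2 * g$d1 * g$d2)
  wp <- wavepacket(matrix(weights[1] * amp, n1, n2) + 0i,
                   matrix(weights[2] * amp, n1, n2) + 0i, g)
  list(model = m, wp = wp)
}

# trajectory with source collection on a small model
source_trajectory <- function(model, wp, t_final_fs, dt_au = 1.5,
                              src_every = 1L) {
  propagate(model, wp, dt = au_to_fs(dt_au),
            n_steps = ceiling(fs_to_au(t_final_fs) / dt_au),
            snapshot_stride = 1000L, collect_source = TRUE,
            source_stride = src_every, cap = no_cap(model))
}
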