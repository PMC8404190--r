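test_that("vertical excitation is an exact component swap", {
  m <- small_coupled_model()
  g <- m$grid
  R1 <- matrix(g$r1, g$n1, g$n2)
  psi <- exp(-R1^2) + 0i
  wp <- wavepacket(psi / sqrt(sum(abs(psi)^2) * g$d1 * g$d2),
                   matrix(0i, g$n1, g$n2), g)
  ex <- vertical_excite(wp)
  expect_equal(wp_norm(ex), wp_norm(wp), tolerance = 1e-14)
  expect_equal(wp_expect(ex), wp_expect(wp), tolerance = 1e-12)
  expect_true(all(ex$psi0 == 0))
  expect_error(vertical_excite(ex), "not entirely on V0")
})

test_that("a zero-length step is the identity", {
  m <- small_coupled_model()
  wp <- small_packet(m)
  out <- step_wavepacket(m, wp, 0)
  expect_identical(out$psi0, wp$psi0)
  expect_identical(out$psi1, wp$psi1)
})

test_that("mean position follows the classical harmonic trajectory", {
  pm <- make_preset("toy_harmonic")
  m <- preset_model(pm)
  g <- m$grid
  wp <- relax_ground_state(m)
  i_sh <- round(0.5 / g$d1)           # displace by whole cells
  x0 <- i_sh * g$d1
  psi <- wp$psi0 * 0
  psi[(1 + i_sh):g$n1, ] <- wp$psi0[1:(g$n1 - i_sh), ]
  wpd <- wavepacket(psi, 0 * psi, g)
  w_au <- ev_to_au(pm$model$omega_ev)
  dt_au <- 0.1
  nst <- ceiling(2 * pi / w_au / dt_au)
  traj <- propagate(m, wpd, dt = au_to_fs(dt_au), n_steps = nst,
                    snapshot_stride = max(1L, nst %/% 40), cap = no_cap(m))
  xs <- vapply(seq_along(traj$snap_times), function(k) {
    d <- abs(traj$snap0[, , k])^2
    sum(rowSums(d) * g$r1) / sum(d)
  }, 0)
  classical <- x0 * cos(w_au * fs_to_au(traj$snap_times))
  expect_lt(max(abs(xs - classical)), 1e-6)
})

test_that("split-operator agrees with the dense matrix-exponential oracle", {
  m <- small_coupled_model(masses = c(500, 500))
  wp <- small_packet(m, p1 = 2, mix = 0)
  dt_au <- 0.1
  U <- dense_propagator(dense_hamiltonian(m), dt_au)
  v <- c(as.vector(wp$psi0), as.vector(wp$psi1))
  wps <- wp
  for (k in 1:50) {
    v <- U %*% v
    wps <- step_wavepacket(m, wps, au_to_fs(dt_au), cap = no_cap(m))
  }
  vs <- c(as.vector(wps$psi0), as.vector(wps$psi1))
  deficit <- 1 - abs(sum(Conj(v) * vs)) * m$grid$d1 * m$grid$d2
  expect_lt(deficit, 1e-8)
})

test_that("Strang splitting converges at second order", {
  m <- small_coupled_model(masses = c(200, 200))
  wp <- small_packet(m)
  H <- dense_hamiltonian(m)
  errs <- vapply(c(2, 1, 0.5), function(dt_au) {
    nst <- round(40 / dt_au)
    U <- dense_propagator(H, dt_au)
    v <- c(as.vector(wp$psi0), as.vector(wp$psi1))
    wps <- wp
    for (k in seq_len(nst)) {
      v <- U %*% v
      wps <- step_wavepacket(m, wps, au_to_fs(dt_au), cap = no_cap(m))
    }
    vs <- c(as.vector(wps$psi0), as.vector(wps$psi1))
    sqrt(sum(abs(v - vs)^2) * m$grid$d1 * m$grid$d2)
  }, 0)
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3.3 & ratios < 4.8))
})

test_that("norm and energy are conserved without an absorber", {
  m <- small_coupled_model(masses = c(500, 500))
  wp <- small_packet(m)
  dt <- 0.1 * AUT_FS
  nst <- ceiling(30 / dt)          # 30 fs at the default step
  traj <- propagate(m, wp, dt = dt, n_steps = nst,
                    snapshot_stride = nst %/% 5, cap = no_cap(m))
  expect_lt(max(abs(traj$pops$P0 + traj$pops$P1 - 1)), 1e-9)
  e0 <- wp_energy(m, wp)
  ns <- length(traj$snap_times)
  es <- vapply(seq_len(ns), function(k)
    wp_energy(m, wavepacket(traj$snap0[, , k], traj$snap1[, , k], m$grid)), 0)
  expect_lt(max(abs(es - e0)), 1e-6)
})

test_that("population accounting closes with the absorber active", {
  pc <- paper_cache()
  po <- pc$traj$pops
  expect_lt(max(abs(po$P0 + po$P1 + po$absorbed - 1)), 1e-8)
  expect_gt(utils::tail(po$absorbed, 1), 0)   # dissociative flux is absorbed
})

test_that("propagate bookkeeping: zero steps and strides", {
  m <- small_coupled_model()
  wp <- small_packet(m)
  t0 <- propagate(m, wp, n_steps = 0)
  expect_identical(length(t0$snap_times), 1L)
  expect_equal(t0$pops$P0[1], wp_population(wp, 0), tolerance = 1e-12)

  tr <- propagate(m, wp, dt = au_to_fs(1), n_steps = 20,
                  snapshot_stride = 5L, collect_source = TRUE,
                  source_stride = 2L, cap = no_cap(m))
  expect_identical(length(tr$snap_times), 5L)    # 0, 5, 10, 15, 20
  expect_identical(ncol(tr$source), 11L)         # every 2 steps
  expect_equal(diff(tr$src_times)[1], au_to_fs(2), tolerance = 1e-12)
})
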