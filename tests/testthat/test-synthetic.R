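test_that("generators are deterministic given a seed and leave the RNG alone", {
  set.seed(123); before <- .Random.seed
  a <- gen_brownian(1e-3, 5, 10, seed = 42)
  expect_identical(before, .Random.seed)
  b <- gen_brownian(1e-3, 5, 10, seed = 42)
  expect_identical(a$traj$coords, b$traj$coords)
  s1 <- gen_shell_exchange(0.02, 10, 20, seed = 42)
  s2 <- gen_shell_exchange(0.02, 10, 20, seed = 42)
  expect_identical(s1$shell$member, s2$shell$member)
  f1 <- gen_solvated_fixture(list(list(name = "r1", n_residues = 4)),
                             1e-3, n_frames = 10, seed = 5)
  f2 <- gen_solvated_fixture(list(list(name = "r1", n_residues = 4)),
                             1e-3, n_frames = 10, seed = 5)
  expect_identical(f1$traj$coords, f2$traj$coords)
})

test_that("Brownian generator: frozen limit, Gaussian steps, MSD slope", {
  z <- gen_brownian(0, 6, 8, seed = 1)
  expect_true(all(z$traj$coords[1, , ] == z$traj$coords[8, , ]))
  expect_error(gen_brownian(-1e-3, 5, 10), ">= 0")
  b <- gen_brownian(1e-3, 400, 400, dt = 1, box = 6, seed = 2)
  unw <- unwrap_coords(b$traj$coords, b$traj$box)
  steps <- unw[-1, , ] - unw[-400, , ]
  expect_equal(mean(steps^2), 2e-3, tolerance = 0.03)
  expect_lt(abs(mean(steps)), 1e-4)
})

test_that("shell exchange: frozen limit and exponential first-exit mean", {
  s0 <- gen_shell_exchange(0, 20, 30, seed = 1)
  expect_true(all(s0$shell$member))
  s <- gen_shell_exchange(0.025, 5000, 600, dt = 1, seed = 3)
  exits <- bf_first_exit_times(s$shell$member, 1)
  expect_equal(mean(exits), 40, tolerance = 0.05)
  ## small-dt expansion of the per-step exit probability
  expect_equal(1 - exp(-0.025 * 0.01), 0.025 * 0.01, tolerance = 1e-3)
})

test_that("telegraph series: stationarity, absorbing limit, correlation time", {
  expect_error(gen_telegraph(0, 0, 5, 10), "> 0")
  ab <- gen_telegraph(0.05, 0, 20, 400, seed = 4)
  on_after <- apply(ab$series, 2, function(col) {
    i <- which(col)[1]
    is.na(i) || all(col[i:length(col)])
  })
  expect_true(all(on_after))
  t <- gen_telegraph(0.025, 0.025, 50, 20000, dt = 1, seed = 5)
  expect_equal(mean(t$series), 0.5, tolerance = 0.02)
  cv <- hb_corr(t$series, 1, max_lag = 120, normalize = "fluctuation")
  expect_equal(one_over_e_time(cv)$tau, 20, tolerance = 0.1)
})

test_that("jump feature: exact CTMC statistics", {
  Q0 <- matrix(0, 3, 3)
  frozen <- gen_jump_feature(Q0, c(1, 2, 3), 0.01, 500, seed = 1)
  expect_equal(length(unique(frozen$states)), 1L)
  expect_lt(max(abs(frozen$feature - frozen$truth$state_centers[frozen$states[1]])), 0.06)
  expect_error(gen_jump_feature(matrix(c(-1, 0.5, 0.5, -1), 2, 2),
                                c(0, 1), 0.1, 10), "sum to 0")
  ## symmetric two-state occupancies 50/50
  Q2 <- matrix(c(-0.02, 0.02, 0.02, -0.02), 2, 2, byrow = TRUE)
  j2 <- gen_jump_feature(Q2, c(0, 1), 0.05, 2e5, dt = 1, seed = 6)
  expect_equal(mean(j2$states == 1), 0.5, tolerance = 0.02)
  ## empirical jump rates match the generator
  Q3 <- matrix(c(-0.03, 0.02, 0.01,
                 0.015, -0.04, 0.025,
                 0.01, 0.02, -0.03), 3, 3, byrow = TRUE)
  j3 <- gen_jump_feature(Q3, c(0, 1, 2), 0.05, 5e5, dt = 1, seed = 7)
  st <- j3$states
  for (i in 1:3) {
    Ti <- sum(st[-length(st)] == i) * 1
    for (k in 1:3) {
      if (i == k) next
      nik <- sum(st[-length(st)] == i & st[-1] == k)
      expect_equal(nik / Ti, Q3[i, k], tolerance = 0.1)
    }
  }
})

test_that("harmonic protein: frozen residues and profile recovery", {
  z <- gen_harmonic_protein(rep(0, 5), 10, seed = 1)
  expect_equal(z$traj$coords[1, , ], z$traj$coords[10, , ])
  expect_error(gen_harmonic_protein(c(0.1, -0.1, 0.1), 10), ">= 0")
  prof <- seq(0.03, 0.15, length.out = 40)
  h <- gen_harmonic_protein(prof, 4000, seed = 2)
  r <- rmsf(h$traj, "all_atom")      # generator adds no rigid-body motion
  expect_gt(cor(r$rmsf, prof), 0.99)
  expect_lt(max(abs(r$rmsf - prof) / prof), 0.05)
})

test_that("double-well Langevin: stability guard, frozen barrier, Boltzmann histogram", {
  expect_error(gen_double_well_langevin(5, gamma = 20, dt = 0.01),
               "dt \\* gamma")
  hi <- gen_double_well_langevin(60, gamma = 5, dt = 0.005,
                                 n_frames = 2e5, seed = 1)
  expect_equal(escape_rate(hi$x, 0.005)$n_transitions, 0L)
  lo <- gen_double_well_langevin(3, gamma = 2, dt = 0.002,
                                 n_frames = 8e5, seed = 2)
  ## equilibrium histogram against the Boltzmann weight of the quartic well
  xs <- lo$x[abs(lo$x) < 2]    # truncation only shifts the normalisation
  h <- hist(xs, breaks = seq(-2, 2, by = 0.1), plot = FALSE)
  keep <- h$counts > 500
  U <- 3 * (h$mids^2 - 1)^2
  lp <- log(h$counts[keep]) - max(log(h$counts[keep]))
  lb <- -U[keep] / lo$truth$RT
  lb <- lb - max(lb)
  expect_gt(cor(lp, lb), 0.99)
  expect_lt(max(abs(lp - lb - mean(lp - lb))), 0.35)
})

test_that("solvated fixture: overlap guard, frozen-solvent flag, D ordering", {
  expect_error(
    gen_solvated_fixture(list(list(name = "a", n_residues = 0)), 1e-3),
    "range|residues|overlap|layout", ignore.case = TRUE)
  fz <- gen_solvated_fixture(list(list(name = "a", n_residues = 4)),
                             solvent_D = 0, shell_cutoff = 0.6,
                             n_frames = 40, seed = 3)
  sh <- shell_membership(fz$traj, fz$regions[["a"]], 0.6)
  sr <- survival_residence(sh)
  expect_true(sr$corr_censored)       # nothing ever leaves
  fx <- gen_solvated_fixture(list(list(name = "fast", n_residues = 4),
                                  list(name = "slow", n_residues = 4)),
                             solvent_D = c(2e-3, 2e-4), shell_cutoff = 0.6,
                             n_shell = 60, n_frames = 300, seed = 4)
  Ds <- vapply(c("fast", "slow"), function(nm) {
    sh <- shell_membership(fx$traj, fx$regions[[nm]], 0.6)
    diffusion_coefficient(fx$traj, members = sh, fit_window = c(1, 6))$D
  }, 0)
  expect_gt(Ds[["fast"]], Ds[["slow"]])
})
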