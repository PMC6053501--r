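test_that("survival correlation matches brute-force episode enumeration", {
  set.seed(31)
  member <- matrix(runif(12 * 6) < 0.7, 12, 6)
  sh <- shell_series(member, dt = 1)
  sr <- survival_residence(sh, max_lag = 5)
  expect_equal(sr$curve$values, bf_survival(member, 5), tolerance = 1e-12)
  expect_equal(sr$tau_hist, mean(bf_first_exit_times(member, 1)),
               tolerance = 1e-12)
  ## first-exit curve is monotone non-increasing and starts at 1
  expect_equal(sr$curve$values[1], 1)
  expect_true(all(diff(sr$curve$values) <= 1e-12))
  ## re-entry mode reproduces the literal product form
  sr2 <- survival_residence(sh, max_lag = 5, allow_reentry = TRUE)
  F <- nrow(member)
  origins <- 1:(F - 5)
  h0 <- member[origins, ]
  manual <- vapply(0:5, function(k) sum(member[origins + k, ] & h0) / sum(h0), 0)
  expect_equal(sr2$curve$values, manual, tolerance = 1e-12)
})

test_that("permanent shell residents give a lower-bound flag", {
  sh <- shell_series(matrix(TRUE, 20, 4), dt = 1)
  sr <- survival_residence(sh, max_lag = 8)
  expect_true(sr$corr_censored)
  expect_true(sr$hist_censored)
  expect_equal(sr$tau_corr, 8)   # reported as the largest lag, flagged
})

test_that("residence estimators recover exponential exit times", {
  s <- gen_shell_exchange(0.025, 4000, 600, dt = 1, seed = 11)
  sr <- survival_residence(s$shell, max_lag = 250)
  expect_equal(sr$tau_corr, 40, tolerance = 0.05)
  expect_equal(sr$tau_hist, 40, tolerance = 0.05)
})

test_that("diffusion: frozen limit, recovery, unit identity, window guards", {
  z <- gen_brownian(0, 10, 40, seed = 1)
  d0 <- diffusion_coefficient(z$traj, fit_window = c(2, 10))
  expect_equal(d0$D, 0, tolerance = 1e-12)
  expect_equal(d0$msd$values[1], 0)
  b <- gen_brownian(1e-3, 500, 600, dt = 1, box = 6, seed = 2)
  d <- diffusion_coefficient(b$traj, fit_window = c(2, 10))
  expect_equal(d$D_nm2ps, 1e-3, tolerance = 0.05)
  expect_equal(d$D, d$D_nm2ps * 1e3, tolerance = 1e-12)
  expect_true(all(d$msd$values >= 0))
  ## linear MSD with near-zero intercept
  expect_lt(abs(d$fit$intercept), 0.05 * max(d$msd$values))
  ## unit identity quoted against a hand conversion
  b2 <- gen_brownian(2.49e-3, 400, 300, dt = 1, box = 6, seed = 3)
  d2 <- diffusion_coefficient(b2$traj, fit_window = c(2, 10))
  expect_equal(d2$D, 2.49, tolerance = 0.06)
  expect_error(diffusion_coefficient(b$traj, fit_window = c(2, 3)),
               "fewer than 5")
})

test_that("shell-restricted MSD uses origin membership only", {
  b <- gen_brownian(1e-3, 60, 200, dt = 1, box = 6, seed = 4)
  member <- matrix(FALSE, 200, 60)
  member[, 1:30] <- TRUE       # half the molecules eligible at any origin
  sh <- shell_series(member, dt = 1)
  d_half <- diffusion_coefficient(b$traj, members = sh,
                                  fit_window = c(2, 10))
  expect_equal(d_half$D_nm2ps, 1e-3, tolerance = 0.15)
  none <- shell_series(matrix(FALSE, 200, 60), dt = 1)
  expect_error(diffusion_coefficient(b$traj, members = none), "no shell")
})

test_that("hydrogen-bond correlation on telegraph data and the geometric criterion", {
  t <- gen_telegraph(0.025, 0.025, 80, 8000, dt = 1, seed = 5)
  cv <- hb_corr(t$series, 1, max_lag = 100, normalize = "fluctuation")
  expect_equal(cv$values[1], 1)
  expect_equal(one_over_e_time(cv)$tau, 20, tolerance = 0.1)
  ## geometry: donor at origin, H along +x, acceptor approaching on +x
  nf <- 6
  atoms <- atom_table(name = c("N", "H", "OW"), resid = c(1, 1, 2),
                      resname = c("ALA", "ALA", "SOL"),
                      mol_id = c(1L, 1L, 2L),
                      mol_class = c("protein", "protein", "solvent"),
                      element = c("N", "H", "O"))
  co <- array(0, dim = c(nf, 3, 3))
  rx <- c(0.30, 0.30, 0.34, 0.40, 0.30, 0.30)  # frame 4 breaks the distance
  for (f in 1:nf) {
    co[f, 1, ] <- c(1, 1, 1)
    co[f, 2, ] <- c(1.1, 1, 1)
    co[f, 3, ] <- c(1 + rx[f], 1, 1)
  }
  co[5, 3, ] <- c(1 + 0.2, 1 + 0.25, 1)        # frame 5 breaks the angle
  tr <- trajectory(atoms, co, c(3, 3, 3), 1)
  hb <- hb_lifetime(tr, donors = cbind(1, 2), acceptors = 3, max_lag = 3)
  expect_false(hb$not_applicable)
  ## indicator: frames 1,2,3,6 bonded; 4 too far; 5 off-angle
  expect_equal(unname(hb$curve$values[1]), 1)
  ## permanent bond -> censored lower bound
  co2 <- co; for (f in 1:nf) co2[f, 3, ] <- c(1.3, 1, 1)
  tr2 <- trajectory(atoms, co2, c(3, 3, 3), 1)
  hb2 <- hb_lifetime(tr2, donors = cbind(1, 2), acceptors = 3, max_lag = 3)
  expect_true(hb2$censored)
  ## apolar system -> not applicable
  hb3 <- hb_lifetime(tr, donors = NULL, acceptors = NULL)
  expect_true(hb3$not_applicable)
})

test_that("P2 reorientation: normalisation, frozen flag, rotational recovery", {
  u <- gen_rotational_diffusion(0.01, 150, 500, dt = 1, seed = 6)
  p <- p2_reorientation(u, dt = 1, max_lag = 120)
  expect_equal(p$curve$values[1], 1)
  expect_equal(p$tau2, 1 / (6 * 0.01), tolerance = 0.1)
  frozen <- array(rep(c(1, 0, 0), each = 40), dim = c(20, 2, 3))
  pf <- p2_reorientation(frozen, dt = 1, max_lag = 10)
  expect_true(pf$censored)
})

test_that("block CIs follow the student-t form", {
  same <- block_ci(rep(3.2, 6))
  expect_equal(same$half_width, 0)
  expect_equal(same$mean, 3.2)
  ## 12 blocks with unit sample SD
  v <- scale(rnorm(12))[, 1] + 5   # mean 5, sd exactly 1
  ci <- block_ci(v)
  expect_equal(ci$half_width, qt(0.975, 11) / sqrt(12), tolerance = 1e-10)
  two <- block_ci(c(0, 2))
  expect_equal(two$mean, 1)
  expect_equal(two$half_width, qt(0.975, 1) * sd(c(0, 2)) / sqrt(2),
               tolerance = 1e-10)
  expect_error(block_ci(5), "at least 2")
})

test_that("CI width shrinks roughly as 1/sqrt(n) with more molecules", {
  width_for <- function(n, seed) {
    s <- gen_shell_exchange(0.025, n, 400, dt = 1, seed = seed)
    groups <- split(seq_len(n), rep(1:25, length.out = n))
    taus <- vapply(groups, function(g) {
      survival_residence(shell_series(s$shell$member[, g, drop = FALSE],
                                      1), max_lag = 180)$tau_hist
    }, 0)
    block_ci(taus)$half_width
  }
  w1 <- mean(vapply(21:23, function(s) width_for(1500, s), 0))
  w2 <- mean(vapply(24:26, function(s) width_for(6000, s), 0))
  expect_equal(w1 / w2, 2, tolerance = 0.25)
})
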