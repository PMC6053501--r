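two_region_traj <- function(coordsA, coordsB, box = 10) {
  ## coordsA/coordsB: frames x 3 positions of two single-atom regions
  nf <- nrow(coordsA)
  atoms <- atom_table(name = c("CA", "CA"), resid = c(1L, 2L),
                      resname = c("ALA", "ALA"), mol_id = c(1L, 1L),
                      mol_class = c("protein", "protein"),
                      element = c("C", "C"))
  co <- array(0, dim = c(nf, 2, 3))
  co[, 1, ] <- coordsA; co[, 2, ] <- coordsB
  trajectory(atoms, co, rep(box, 3), 1)
}

test_that("minimum-distance feature: pairwise case, symmetry, brute force", {
  set.seed(41)
  A <- matrix(runif(30, 0, 10), 10, 3)
  B <- matrix(runif(30, 0, 10), 10, 3)
  tr <- two_region_traj(A, B)
  r1 <- region_spec("a", "helix", c(1, 1), "Ext")
  r2 <- region_spec("b", "helix", c(2, 2), "Ext")
  f <- min_distance_feature(tr, r1, r2)
  manual <- vapply(1:10, function(i) {
    sqrt(sum(bf_min_image(A[i, ], B[i, ], rep(10, 3))^2))
  }, 0)
  expect_equal(f, manual, tolerance = 1e-12)
  expect_equal(min_distance_feature(tr, r2, r1), f)
  ## multi-atom brute force
  fx <- gen_solvated_fixture(list(list(name = "p", n_residues = 5),
                                  list(name = "q", n_residues = 5)),
                             1e-3, n_frames = 10, seed = 2)
  fq <- min_distance_feature(fx$traj, fx$regions[["p"]], fx$regions[["q"]])
  rowsp <- region_atom_rows(fx$traj, fx$regions[["p"]])
  rowsq <- region_atom_rows(fx$traj, fx$regions[["q"]])
  manual2 <- vapply(1:10, function(fr) {
    best <- Inf
    for (i in rowsp) for (j in rowsq) {
      d <- bf_min_image(fx$traj$coords[fr, i, ], fx$traj$coords[fr, j, ],
                        fx$traj$box[fr, ])
      best <- min(best, sqrt(sum(d^2)))
    }
    best
  }, 0)
  expect_equal(fq, manual2, tolerance = 1e-12)
})

test_that("discretisation: bin arithmetic, dense remap, guards", {
  s <- c(seq(0, 0.999, length.out = 200), 0.55)
  d <- discretize_feature(s, 10)
  expect_equal(length(d$dtraj), 201)
  expect_equal(d$centers[d$dtraj[201]], 0.55, tolerance = 0.051)
  expect_error(discretize_feature(rep(1, 10)), "constant")
  ## empty bins removed with dense remapping, frame count preserved
  gap <- c(runif(50, 0, 0.3), runif(50, 0.7, 1.0))
  dg <- discretize_feature(gap, 10)
  expect_equal(sort(unique(dg$dtraj)), seq_along(dg$centers))
  expect_equal(length(dg$dtraj), 100)
})

test_that("MSM estimation: degenerate chains, exact counting, propagator", {
  expect_equal(estimate_msm(rep(1L, 50), lag = 1)$T, matrix(1, 1, 1))
  alt <- rep(c(1L, 2L), 30)
  m <- estimate_msm(alt, lag = 1, reversible = FALSE)
  expect_equal(m$T, rbind(c(0, 1), c(1, 0)))
  ## reversible estimate satisfies detailed balance
  set.seed(42)
  Q3 <- matrix(c(-0.05, 0.03, 0.02,
                 0.02, -0.06, 0.04,
                 0.03, 0.03, -0.06), 3, 3, byrow = TRUE)
  j <- gen_jump_feature(Q3, c(0, 1, 2), 0.05, 2e5, dt = 1, seed = 3)
  d <- discretize_feature(j$feature, 12)
  mm <- estimate_msm(d$dtraj, lag = 4)
  db <- outer(mm$pi, rep(1, nrow(mm$T))) * mm$T
  expect_lt(max(abs(db - t(db))), 1e-8)
  ## hidden-state propagator against the exact matrix exponential
  mm_states <- estimate_msm(j$states, lag = 5)
  expect_equal(mm_states$T, bf_expm(Q3 * 5), tolerance = 0.07)
})

test_that("implied timescales: closed form and Markovian flatness", {
  ## chain with lambda2 = 0.8 per frame, 15 ns frames
  set.seed(43)
  Tm <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  n <- 2e5
  st <- integer(n); st[1] <- 1L
  u <- runif(n)
  for (i in 2:n) st[i] <- if (u[i] < Tm[st[i - 1L], 1]) 1L else 2L
  its <- implied_timescales(st, lags = 1L, k = 1, dt = 15)
  expect_equal(its$its[1], -15 / log(0.8), tolerance = 0.05)
  ## flat in lag for Markovian data
  its_multi <- implied_timescales(st, lags = c(1L, 2L, 4L, 8L), k = 1,
                                  dt = 15)
  expect_lt(diff(range(its_multi$its)) / mean(its_multi$its), 0.1)
})

test_that("PCCA+ memberships: crisp blocks, perturbation, simplex rows", {
  blockT <- function(eps) {
    ## within-block uniform (1-eps)/3, off-block mass eps spread evenly
    Tm <- matrix(eps / 6, 9, 9)
    for (b in 0:2) Tm[b * 3 + 1:3, b * 3 + 1:3] <- (1 - eps) / 3
    Tm
  }
  T0 <- blockT(0)
  chi0 <- pcca_coarse(T0, 3)
  expect_equal(rowSums(chi0), rep(1, 9), tolerance = 1e-10)
  crisp <- apply(chi0, 1, max)
  expect_true(all(crisp > 0.999))
  labs <- apply(chi0, 1, which.max)
  expect_equal(length(unique(labs[1:3])), 1L)
  expect_equal(length(unique(labs)), 3L)
  Tw <- blockT(0.02)
  chiw <- pcca_coarse(Tw, 3)
  expect_equal(rowSums(chiw), rep(1, 9), tolerance = 1e-10)
  expect_true(all(apply(chiw, 1, max) > 0.95))
})

test_that("HMM refinement recovers a generated hidden chain", {
  ## 3 hidden states with Gaussian emissions, discretised
  A_true <- rbind(c(0.97, 0.02, 0.01),
                  c(0.02, 0.96, 0.02),
                  c(0.01, 0.03, 0.96))
  set.seed(44)
  n <- 6e4
  st <- integer(n); st[1] <- 1L
  for (i in 2:n) st[i] <- sample.int(3, 1, prob = A_true[st[i - 1L], ])
  obs <- c(1.0, 1.6, 2.4)[st] + rnorm(n, sd = 0.12)
  d <- discretize_feature(obs, 40)
  hm <- hmm_refine(d$dtraj, n_hidden = 3, lag = 1,
                   obs_centers = d$centers)
  ## EM likelihood is non-decreasing
  expect_true(all(diff(hm$loglik) > -1e-6))
  expect_equal(hm$T_coarse, A_true, tolerance = 0.1)
  ## populations match empirical dwell fractions
  emp <- tabulate(st, 3) / n
  expect_equal(hm$populations, emp, tolerance = 0.03)
  ## canonical ordering: mean feature increases with state index
  expect_true(all(diff(hm$mean_feature) > 0))
})

test_that("transition rates: arithmetic and identity matrix", {
  Tc <- rbind(c(0.85, 0.15), c(0.1, 0.9))
  k <- transition_rates(Tc, 15)
  expect_equal(k[1, 2], 10)
  expect_equal(k[2, 1], 0.1 / 15 * 1e3)
  expect_true(is.na(k[1, 1]))
  k0 <- transition_rates(diag(3), 15)
  expect_true(all(k0[!is.na(k0)] == 0))
  expect_error(transition_rates(rbind(c(0.5, 0.1), c(0, 1)), 15),
               "row-stochastic")
})

test_that("coarse rates are stable in the microstate bin count", {
  Q <- matrix(c(-0.020, 0.014, 0.006,
                0.012, -0.024, 0.012,
                0.005, 0.015, -0.020), 3, 3, byrow = TRUE)
  j <- gen_jump_feature(Q, c(1.0, 1.5, 2.2), 0.08, 2e5, dt = 1, seed = 8)
  rates_for <- function(nb) {
    d <- discretize_feature(j$feature, nb)
    hm <- hmm_refine(d$dtraj, 3, lag = 3, obs_centers = d$centers)
    transition_rates(hm$T_coarse, 3)
  }
  k30 <- rates_for(30)
  k100 <- rates_for(100)
  off <- !is.na(k30)
  expect_lt(max(abs(k30[off] - k100[off]) / pmax(k30[off], 1)), 0.2)
})

test_that("bootstrap requires multiple trajectories and reports spreads", {
  Q <- matrix(c(-0.03, 0.02, 0.01,
                0.02, -0.04, 0.02,
                0.01, 0.03, -0.04), 3, 3, byrow = TRUE)
  dtrajs <- lapply(1:3, function(s) {
    j <- gen_jump_feature(Q, c(1, 1.5, 2.2), 0.08, 3e4, dt = 1, seed = s)
    discretize_feature(j$feature, 25)$dtraj
  })
  expect_error(bootstrap_rates(dtrajs[1], lag = 3, dt_ns = 1),
               "at least 2")
  br <- bootstrap_rates(dtrajs, lag = 3, dt_ns = 1, n_boot = 3, seed = 9)
  off <- !is.na(br$rate_sd)
  expect_true(all(br$rate_sd[off] >= 0))
  expect_equal(dim(br$rates), c(3, 3))
})
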