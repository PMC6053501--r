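## Synthetic-trajectory generators with known ground truth. Each
## generator emulates exactly the statistical structure one estimator
## assumes -- Brownian solvent for MSD fitting, exponential shell exit
## for residence times, a telegraph process for hydrogen-bond indicator
## series, a Markov jump process for the conformational feature,
## isotropic harmonic fluctuations for RMSF, and overdamped double-well
## Langevin dynamics for Kramers-rate scaling -- and nothing more.
## All randomness flows from one explicit seed per call; the caller's
## RNG state is left untouched.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

solvent_particle_atoms <- function(n) {
  atom_table(name = rep("S", n), resid = seq_len(n),
             resname = rep("SLV", n), mol_id = seq_len(n),
             mol_class = rep("solvent", n), element = rep("X", n))
}

#' Brownian solvent trajectory with known diffusion coefficient
#'
#' Independent particles performing free Brownian motion: per-frame
#' displacements are i.i.d. Gaussian with per-axis variance
#' `2 * D_true * dt`. Coordinates are stored wrapped into the periodic
#' box; the analytic MSD is `6 * D_true * t`.
#'
#' @param D_true Diffusion coefficient, nm^2/ps (>= 0; 0 freezes all
#'   particles).
#' @param n_particles Number of solvent particles.
#' @param n_frames Number of frames (>= 3).
#' @param dt Frame spacing, ps.
#' @param box Cubic box edge (scalar) or length-3 edges, nm.
#' @param seed RNG seed (default 7).
#' @return List with `traj` (a `solv_trajectory`) and `truth`
#'   (`list(D_true = ...)`).
#' @export
gen_brownian <- function(D_true, n_particles, n_frames, dt = 1, box = 5,
                         seed = 7) {
  if (!is.numeric(D_true) || D_true < 0) stop("D_true must be >= 0")
  if (n_frames < 3) stop("n_frames must be >= 3")
  if (length(box) == 1L) box <- rep(box, 3)
  with_seed(seed, {
    sdstep <- sqrt(2 * D_true * dt)
    coords <- array(0, dim = c(n_frames, n_particles, 3))
    for (k in 1:3) {
      x0 <- runif(n_particles, 0, box[k])
      steps <- matrix(rnorm((n_frames - 1L) * n_particles, sd = sdstep),
                      n_frames - 1L, n_particles)
      unw <- apply(rbind(x0, steps), 2, cumsum)
      coords[, , k] <- unw %% box[k]
    }
    list(traj = trajectory(solvent_particle_atoms(n_particles), coords,
                           box, dt),
         truth = list(D_true = D_true))
  })
}

#' Shell occupancy series with exponential exit kinetics
#'
#' Every molecule starts inside the shell; per frame it leaves with
#' probability `1 - exp(-lambda_exit * dt)` (the exact discretisation of
#' a Poisson exit process), so first-exit times are geometric with mean
#' `dt / (1 - exp(-lambda_exit * dt)) ~ 1/lambda_exit`. An optional
#' re-entry rate turns the series into a stationary two-state process.
#'
#' @param lambda_exit Exit rate, ps^-1 (>= 0).
#' @param n_molecules Number of molecules.
#' @param n_frames Number of frames.
#' @param dt Frame spacing, ps.
#' @param reentry_rate Re-entry rate, ps^-1 (default 0: absorbing exit).
#' @param seed RNG seed.
#' @return List with `shell` (a `shell_series`) and `truth`.
#' @export
gen_shell_exchange <- function(lambda_exit, n_molecules, n_frames, dt = 1,
                               reentry_rate = 0, seed = 7) {
  if (lambda_exit < 0) stop("lambda_exit must be >= 0")
  if (reentry_rate < 0) stop("reentry_rate must be >= 0")
  with_seed(seed, {
    p_exit <- 1 - exp(-lambda_exit * dt)
    member <- matrix(FALSE, n_frames, n_molecules)
    if (reentry_rate == 0) {
      if (p_exit == 0) {
        member[] <- TRUE
      } else {
        k <- rgeom(n_molecules, p_exit) + 1L   # frames survived inside
        fr <- seq_len(n_frames)
        member <- outer(fr, k, function(f, kk) f <= kk)
      }
    } else {
      p_in <- 1 - exp(-reentry_rate * dt)
      state <- rep(TRUE, n_molecules)
      member[1, ] <- state
      for (f in 2:n_frames) {
        u <- runif(n_molecules)
        state <- ifelse(state, u > p_exit, u < p_in)
        member[f, ] <- state
      }
    }
    list(shell = shell_series(member, dt = dt),
         truth = list(lambda_exit = lambda_exit,
                      reentry_rate = reentry_rate,
                      tau_true = if (lambda_exit > 0) 1 / lambda_exit else Inf))
  })
}

#' Telegraph (two-state Markov) hydrogen-bond indicator series
#'
#' Stationary on/off series mimicking a hydrogen-bond indicator: switch
#' rates `k_on` (off -> on) and `k_off` (on -> off). Sampling uses the
#' exact two-state propagator at `dt`, so the normalized fluctuation
#' autocorrelation decays as `exp(-(k_on + k_off) t)` with no
#' discretisation bias, and the stationary occupancy is
#' `k_on / (k_on + k_off)`.
#'
#' @param k_on,k_off Switching rates, ps^-1 (sum must be > 0).
#' @param n_pairs Number of independent series.
#' @param n_frames Frames per series.
#' @param dt Frame spacing, ps.
#' @param seed RNG seed.
#' @return List with `series` (frames x pairs logical matrix), `dt` and
#'   `truth` (rates, occupancy, correlation time `1/(k_on+k_off)`).
#' @export
gen_telegraph <- function(k_on, k_off, n_pairs, n_frames, dt = 1, seed = 7) {
  if (k_on < 0 || k_off < 0) stop("rates must be >= 0")
  if (k_on + k_off == 0) stop("k_on + k_off must be > 0")
  with_seed(seed, {
    kappa <- k_on + k_off
    p1 <- k_on / kappa
    decay <- exp(-kappa * dt)
    p_on_on <- p1 + (1 - p1) * decay     # stay on
    p_off_on <- p1 * (1 - decay)         # off -> on
    h <- matrix(FALSE, n_frames, n_pairs)
    state <- runif(n_pairs) < p1
    h[1, ] <- state
    for (f in seq_len(n_frames)[-1]) {
      u <- runif(n_pairs)
      state <- ifelse(state, u < p_on_on, u < p_off_on)
      h[f, ] <- state
    }
    list(series = h, dt = dt,
         truth = list(k_on = k_on, k_off = k_off, occupancy = p1,
                      tau_corr = 1 / kappa))
  })
}

#' One-dimensional feature hopping between metastable states
#'
#' A continuous-time Markov jump process over `k` hidden states (exact
#' simulation: exponential waiting times, then sampling on the frame
#' grid, so there is no time-discretisation bias), observed as
#' `center[state] + Gaussian noise`. Emulates an inter-region distance
#' feature switching between closed / crystallographic / open
#' conformations.
#'
#' @param rate_matrix k x k generator, ns^-1: off-diagonals >= 0, rows
#'   summing to zero.
#' @param state_centers Feature value per state, nm.
#' @param noise_sd Observation noise SD, nm.
#' @param n_frames Number of frames.
#' @param dt Frame spacing in ns (note: this generator works on the
#'   conformational timescale, hence ns).
#' @param seed RNG seed.
#' @return List with `feature` (numeric vector), `states` (integer
#'   vector), `dt_ns` and `truth`.
#' @export
gen_jump_feature <- function(rate_matrix, state_centers, noise_sd,
                             n_frames, dt = 1, seed = 7) {
  Q <- as.matrix(rate_matrix)
  k <- nrow(Q)
  if (ncol(Q) != k) stop("rate_matrix must be square")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-10 * max(1, max(abs(Q)))))
    stop("rate_matrix rows must sum to 0 (generator form)")
  if (length(state_centers) != k)
    stop("state_centers must have one value per state")
  with_seed(seed, {
    pi0 <- ctmc_stationary(Q)
    total <- n_frames * dt
    t_jump <- 0; s <- sample.int(k, 1, prob = pi0)
    jump_times <- 0; jump_states <- s
    while (t_jump < total) {
      exit <- -Q[s, s]
      if (exit <= 0) break
      t_jump <- t_jump + rexp(1, exit)
      if (t_jump >= total) break
      s <- sample.int(k, 1, prob = pmax(off[s, ], 0))
      jump_times <- c(jump_times, t_jump)
      jump_states <- c(jump_states, s)
    }
    ft <- (seq_len(n_frames) - 1) * dt
    states <- jump_states[findInterval(ft, jump_times)]
    feature <- state_centers[states] + rnorm(n_frames, sd = noise_sd)
    list(feature = feature, states = states, dt_ns = dt,
         truth = list(rate_matrix = Q, state_centers = state_centers,
                      noise_sd = noise_sd, stationary = pi0))
  })
}

ctmc_stationary <- function(Q) {
  k <- nrow(Q)
  if (all(Q == 0)) return(rep(1 / k, k))  # every distribution stationary
  p <- tryCatch(qr.solve(rbind(t(Q), rep(1, k)), c(rep(0, k), 1)),
                error = function(e) rep(1 / k, k))
  p <- pmax(p, 0)
  p / sum(p)
}

#' Harmonic protein with a prescribed RMSF profile
#'
#' One C-alpha pseudo-atom per residue, fluctuating isotropically and
#' independently about fixed mean positions (laid out on a gentle helix
#' so superposition fits are non-degenerate). Per-coordinate SD is
#' `rmsf_profile / sqrt(3)`, so the measured all-atom RMSF recovers the
#' input profile.
#'
#' @param rmsf_profile Per-residue RMSF targets, nm (>= 0).
#' @param n_frames Number of frames.
#' @param dt Frame spacing, ps.
#' @param seed RNG seed.
#' @return List with `traj` and `truth` (the profile).
#' @export
gen_harmonic_protein <- function(rmsf_profile, n_frames, dt = 1, seed = 7) {
  if (any(rmsf_profile < 0)) stop("rmsf values must be >= 0")
  n <- length(rmsf_profile)
  if (n < 3) stop("need at least 3 residues")
  with_seed(seed, {
    i <- seq_len(n)
    base <- cbind(0.38 * i, 0.6 * sin(i / 3), 0.6 * cos(i / 3))
    base <- sweep(base, 2, apply(base, 2, min)) + 2   # keep inside the box
    sdc <- rmsf_profile / sqrt(3)
    coords <- array(0, dim = c(n_frames, n, 3))
    for (k in 1:3) {
      noise <- matrix(rnorm(n_frames * n), n_frames, n)
      coords[, , k] <- sweep(noise, 2, sdc, `*`) +
        matrix(base[, k], n_frames, n, byrow = TRUE)
    }
    box <- apply(base, 2, max) + 2
    atoms <- atom_table(name = rep("CA", n), resid = i,
                        resname = rep("ALA", n), mol_id = rep(1L, n),
                        mol_class = rep("protein", n),
                        element = rep("C", n))
    list(traj = trajectory(atoms, coords, box, dt),
         truth = list(rmsf_profile = rmsf_profile))
  })
}

#' Overdamped double-well Langevin dynamics
#'
#' Euler--Maruyama integration of `gamma dx/dt = -U'(x) + noise` in the
#' quartic double well `U(x) = H_star * (x^2 - 1)^2`, whose barrier
#' height between the wells at x = -1 and x = +1 equals `H_star`.
#' Because the overdamped equation is a pure time rescaling in `gamma`,
#' the well-to-well escape rate scales exactly as `1/gamma` -- the
#' high-friction Kramers limit -- making this the test bed for
#' viscosity-dependent rate relations.
#'
#' @param H_star Barrier height, kJ/mol.
#' @param gamma Friction coefficient, ps^-1 (> 0).
#' @param temperature Temperature, K.
#' @param dt Integration step, ps; must satisfy `dt * gamma < 0.1`.
#' @param n_frames Number of steps.
#' @param seed RNG seed.
#' @param x0 Initial position (default -1, a well bottom).
#' @return List with `x` (the series), `dt`, and `truth`.
#' @export
gen_double_well_langevin <- function(H_star, gamma, temperature = 300,
                                     dt = 0.01, n_frames = 1e5, seed = 7,
                                     x0 = -1) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (H_star < 0) stop("H_star must be >= 0")
  if (dt * gamma >= 0.1)
    stop("unstable integration step: dt * gamma must be < 0.1 ",
         "(use dt < ", format(0.1 / gamma, digits = 3), " ps)")
  RT <- 8.314462618e-3 * temperature   # kJ/mol
  with_seed(seed, {
    noise <- rnorm(n_frames)
    x <- langevin_double_well(n_frames, x0, H_star, gamma, RT, dt, noise)
    list(x = x, dt = dt,
         truth = list(H_star = H_star, gamma = gamma,
                      temperature = temperature, RT = RT))
  })
}

#' Solvated fixture: labelled rigid regions plus Brownian solvent
#'
#' End-to-end test stand-in for a protein-in-solvent system: each region
#' is a rigid cluster of C-alpha pseudo-atoms at a distinct location, and
#' each region is surrounded by its own population of Brownian solvent
#' particles with a region-specific diffusion coefficient, initialised
#' inside the shell cutoff. The whole pipeline can then be asked to rank
#' local diffusion coefficients, with the truth known by construction.
#'
#' @param region_layout List of regions, each a list with `name`,
#'   `n_residues` and optionally `klass`/`exposure`.
#' @param solvent_D Diffusion coefficient(s), nm^2/ps: scalar or one per
#'   region.
#' @param shell_cutoff Shell cutoff, nm.
#' @param n_shell Solvent particles per region.
#' @param n_frames,dt Frames and spacing (ps).
#' @param box Cubic box edge, nm.
#' @param seed RNG seed.
#' @return List with `traj`, `regions` (a `region_map`) and `truth`.
#' @export
gen_solvated_fixture <- function(region_layout, solvent_D, shell_cutoff = 0.5,
                                 n_shell = 40, n_frames = 200, dt = 1,
                                 box = 8, seed = 7) {
  nr <- length(region_layout)
  if (nr < 1) stop("layout must define at least one region")
  D <- rep(solvent_D, length.out = nr)
  with_seed(seed, {
    ## rigid region clusters on a circle in the box midplane
    ang <- 2 * pi * (seq_len(nr) - 1) / max(nr, 2)
    centers <- cbind(box / 2 + box / 4 * cos(ang),
                     box / 2 + box / 4 * sin(ang), box / 2)
    prot <- list(); resid0 <- 0L
    ranges <- list()
    for (r in seq_len(nr)) {
      nres <- region_layout[[r]]$n_residues
      i <- seq_len(nres)
      xyz <- cbind(centers[r, 1] + 0.2 * cos(i), centers[r, 2] + 0.2 * sin(i),
                   centers[r, 3] + 0.15 * (i - mean(i)))
      prot[[r]] <- xyz
      ranges[[r]] <- c(resid0 + 1L, resid0 + nres)
      resid0 <- resid0 + nres
    }
    for (r in seq_len(nr)) for (s in seq_len(nr)) {
      if (r < s && any(ranges[[r]][1]:ranges[[r]][2] %in%
                         ranges[[s]][1]:ranges[[s]][2]))
        stop("overlapping regions in layout")
    }
    pxyz <- do.call(rbind, prot)
    np <- nrow(pxyz)
    ## solvent: per-region populations started inside the shell
    ns_tot <- n_shell * nr
    scoords <- array(0, dim = c(n_frames, ns_tot, 3))
    for (r in seq_len(nr)) {
      cols <- (r - 1L) * n_shell + seq_len(n_shell)
      sdstep <- sqrt(2 * D[r] * dt)
      for (k in 1:3) {
        x0 <- centers[r, k] + runif(n_shell, -shell_cutoff / 2,
                                    shell_cutoff / 2)
        steps <- matrix(rnorm((n_frames - 1L) * n_shell, sd = sdstep),
                        n_frames - 1L, n_shell)
        scoords[, cols, k] <- apply(rbind(x0, steps), 2, cumsum) %% box
      }
    }
    nres_tot <- resid0
    atoms <- atom_table(
      name = c(rep("CA", np), rep("S", ns_tot)),
      resid = c(rep(seq_len(nres_tot),
                    times = 1), nres_tot + seq_len(ns_tot)),
      resname = c(rep("ALA", np), rep("SLV", ns_tot)),
      mol_id = c(rep(1L, np), 1L + seq_len(ns_tot)),
      mol_class = c(rep("protein", np), rep("solvent", ns_tot)),
      element = c(rep("C", np), rep("X", ns_tot)))
    coords <- array(0, dim = c(n_frames, np + ns_tot, 3))
    for (f in seq_len(n_frames)) coords[f, seq_len(np), ] <- pxyz
    coords[, np + seq_len(ns_tot), ] <- scoords
    regs <- region_map(lapply(seq_len(nr), function(r) {
      e <- region_layout[[r]]
      region_spec(e$name, e$klass %||% "helix", ranges[[r]],
                  e$exposure %||% "Ext", cutoff_nm = shell_cutoff)
    }))
    list(traj = trajectory(atoms, coords, box, dt), regions = regs,
         truth = list(solvent_D = D, shell_cutoff = shell_cutoff,
                      centers = centers))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
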