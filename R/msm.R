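## Conformational kinetics from a 1-D inter-region distance feature:
## microstate Markov state model (reversible maximum-likelihood
## estimation), implied timescales, PCCA+ coarse-graining into three
## metastable states, a discrete-output hidden Markov refinement fitted
## by expectation-maximisation, and transition rates with bootstrap
## uncertainties.

#' Minimum inter-region distance feature
#'
#' Per frame, the minimum minimum-image distance between any atom of
#' region A and any atom of region B (heavy atoms only by default).
#'
#' @param traj A `solv_trajectory`.
#' @param regionA,regionB `region_spec`s (non-empty).
#' @param heavy_only Exclude hydrogens (default TRUE).
#' @return Numeric vector of distances (nm), one per frame.
#' @export
min_distance_feature <- function(traj, regionA, regionB,
                                 heavy_only = TRUE) {
  ra <- region_atom_rows(traj, regionA)
  rb <- region_atom_rows(traj, regionB)
  if (heavy_only) {
    ra <- ra[traj$atoms$element[ra] != "H"]
    rb <- rb[traj$atoms$element[rb] != "H"]
  }
  if (!length(ra) || !length(rb)) stop("empty region after atom filtering")
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    A <- matrix(traj$coords[f, ra, ], ncol = 3)
    B <- matrix(traj$coords[f, rb, ], ncol = 3)
    box <- traj$box[f, ]
    best <- Inf
    for (j in seq_len(nrow(B))) {
      d2 <- 0
      for (k in 1:3) {
        d <- A[, k] - B[j, k]
        d <- d - box[k] * round(d / box[k])
        d2 <- d2 + d * d
      }
      best <- min(best, min(d2))
    }
    out[f] <- sqrt(best)
  }
  out
}

#' Discretise a 1-D feature series into microstates
#'
#' Uniform bins over the observed range; empty bins are removed and the
#' indices remapped densely, preserving the frame count.
#'
#' @param series Numeric feature vector (non-constant).
#' @param n_bins Number of bins (>= 2, default 60).
#' @return List with `dtraj` (integer microstates 1..S), `centers` (bin
#'   centres of the retained bins, nm) and `breaks`.
#' @export
discretize_feature <- function(series, n_bins = 60) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  rng <- range(series)
  if (diff(rng) == 0) stop("feature series is constant; cannot discretise")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  raw <- findInterval(series, breaks, rightmost.closed = TRUE)
  keep <- sort(unique(raw))
  if (length(keep) < 2) stop("all frames fall in one bin")
  dtraj <- match(raw, keep)
  centers <- (breaks[-1] + breaks[-length(breaks)])[keep] / 2
  list(dtraj = as.integer(dtraj), centers = centers, breaks = breaks)
}

count_matrix <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  S <- if (is.null(n_states)) max(unlist(lapply(dtrajs, max))) else n_states
  C <- matrix(0, S, S)
  for (d in dtrajs) {
    Tn <- length(d)
    if (Tn <= lag) next
    i <- d[seq_len(Tn - lag)]
    j <- d[seq_len(Tn - lag) + lag]
    C <- C + unclass(table(factor(i, levels = 1:S),
                           factor(j, levels = 1:S)))
  }
  unname(C)
}

largest_connected <- function(C) {
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  members <- which(comp$membership ==
                     which.max(tabulate(comp$membership)))
  sort(members)
}

## Reversible maximum-likelihood transition matrix via the standard
## fixed-point iteration on the symmetric flux matrix.
reversible_mle <- function(C, tol = 1e-10, max_iter = 10000) {
  ci <- rowSums(C)
  X <- C + t(C)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, `+`)
    X <- (C + t(C)) / denom
    X[C + t(C) == 0] <- 0
    Tm <- X / rowSums(X)
    ll <- sum(C[C > 0] * log(Tm[C > 0]))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  Tm
}

#' Estimate a microstate Markov state model
#'
#' Sliding-window transition counts at the given lag, restricted to the
#' largest strongly connected set of microstates, followed by either the
#' reversible maximum-likelihood transition matrix (fixed-point
#' iteration, likelihood tolerance 1e-10) or plain row normalisation.
#'
#' @param dtrajs Integer microstate trajectory or list of them
#'   (states 1..S).
#' @param lag Lag in frames (>= 1).
#' @param reversible Reversible estimation (default TRUE).
#' @return List of class `msm_model`: `T` (row-stochastic), `pi`
#'   (stationary distribution), `active` (microstates retained), `C`
#'   (counts on the active set), `lag`.
#' @export
estimate_msm <- function(dtrajs, lag, reversible = TRUE) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  C <- count_matrix(dtrajs, lag)
  active <- largest_connected(C)
  if (length(active) < 1 || sum(C) == 0)
    stop("no transition counts at this lag")
  Ca <- C[active, active, drop = FALSE]
  if (length(active) == 1L) {
    ## degenerate single-state chain
    return(structure(list(T = matrix(1, 1, 1), pi = 1, active = active,
                          C = Ca, lag = lag), class = "msm_model"))
  }
  Tm <- if (reversible) reversible_mle(Ca) else Ca / rowSums(Ca)
  pi <- stationary_distribution(Tm)
  structure(list(T = Tm, pi = pi, active = active, C = Ca, lag = lag),
            class = "msm_model")
}

stationary_distribution <- function(Tm) {
  e <- eigen(t(Tm))
  i <- which.min(abs(e$values - 1))
  p <- abs(Re(e$vectors[, i]))
  p / sum(p)
}

#' Implied timescales across lags
#'
#' t_i(tau) = -tau / log(lambda_i(tau)) for the k largest non-trivial
#' eigenvalues of the lag-tau transition matrix. Flatness in tau
#' diagnoses Markovianity. Eigenvalues >= 1 give an infinite timescale,
#' reported as Inf (upper-bound flag); eigenvalues <= 0 give NA.
#'
#' @param dtrajs Microstate trajectory (or list).
#' @param lags Integer lags in frames.
#' @param k Number of timescales (default 2).
#' @param dt Time per frame (sets the output unit; e.g. ns per frame).
#' @param reversible Reversible estimation (default TRUE); complex
#'   eigenvalues beyond tolerance then raise an error.
#' @return data.frame with `lag` (frames), `lag_time`, `index`, `its`.
#' @export
implied_timescales <- function(dtrajs, lags, k = 2, dt = 1,
                               reversible = TRUE) {
  out <- NULL
  for (lg in lags) {
    m <- estimate_msm(dtrajs, lg, reversible = reversible)
    ev <- eigen(m$T, only.values = TRUE)$values
    if (reversible && any(abs(Im(ev)) > 1e-8))
      stop("complex eigenvalues in reversible transition matrix")
    ev <- Re(ev)[order(-abs(Re(ev)))]
    lam <- ev[seq_len(min(k, length(ev) - 1L)) + 1L]
    its <- ifelse(lam >= 1, Inf,
                  ifelse(lam <= 0, NA_real_, -lg * dt / log(lam)))
    out <- rbind(out, data.frame(lag = lg, lag_time = lg * dt,
                                 index = seq_along(its) + 1L, its = its))
  }
  out
}

#' PCCA+ memberships of microstates into metastable states
#'
#' Fuzzy spectral clustering of a reversible transition matrix: the top
#' `n_meta` right eigenvectors span a simplex whose vertices are located
#' by the inner-simplex (maximal-spread row) search; memberships are the
#' barycentric coordinates, clipped to [0, 1] and renormalised so every
#' row sums to 1. In the decoupled (block-diagonal) limit the
#' memberships are crisp 0/1 indicators of the blocks.
#'
#' @param T_micro Row-stochastic (irreducible) matrix.
#' @param n_meta Number of metastable states (default 3).
#' @return n_micro x n_meta membership matrix; attribute
#'   `"spectral_gap_warning"` is set when lambda_{n_meta} and
#'   lambda_{n_meta+1} are closer than 1e-6.
#' @export
pcca_coarse <- function(T_micro, n_meta = 3) {
  n <- nrow(T_micro)
  if (n_meta > n) stop("n_meta cannot exceed the number of microstates")
  pi <- stationary_distribution(T_micro)
  ## floor the weights so exactly decoupled (reducible) chains, whose
  ## stationary vector is supported on one block, remain tractable
  pi <- pmax(pi, 1e-10)
  pi <- pi / sum(pi)
  ## symmetrise with the stationary weights: real spectrum, orthogonal
  ## eigenvectors; right eigenvectors of T recovered by rescaling
  s <- sqrt(pi)
  Sym <- diag(s) %*% T_micro %*% diag(1 / s)
  Sym <- (Sym + t(Sym)) / 2
  e <- eigen(Sym, symmetric = TRUE)
  ord <- order(-e$values)
  vals <- e$values[ord]
  gap_warn <- (length(vals) > n_meta) &&
    abs(vals[n_meta] - vals[n_meta + 1]) < 1e-6
  X <- (1 / s) * e$vectors[, ord[seq_len(n_meta)], drop = FALSE]
  X[, 1] <- 1                                  # the trivial eigenvector
  ## inner-simplex vertex search
  idx <- integer(n_meta)
  Y <- X
  idx[1] <- which.max(rowSums(Y^2))
  Y <- sweep(Y, 2, X[idx[1], ])
  if (n_meta > 1) {
    for (j in 2:n_meta) {
      idx[j] <- which.max(rowSums(Y^2))
      v <- Y[idx[j], ]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) stop("degenerate eigenvector structure in PCCA+")
      v <- v / nv
      Y <- Y - outer(drop(Y %*% v), v)
    }
  }
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  rs <- rowSums(chi)
  rs[rs == 0] <- 1
  chi <- chi / rs
  attr(chi, "spectral_gap_warning") <- gap_warn
  chi
}

coarse_grain_T <- function(Tm, pi, chi) {
  num <- t(chi) %*% (pi * Tm) %*% chi
  den <- drop(t(chi) %*% pi)
  A <- num / den
  A / rowSums(A)
}

#' Hidden Markov refinement of the coarse-grained kinetic model
#'
#' Discrete-output hidden Markov model over the microstate symbols,
#' estimated by expectation--maximisation (Baum--Welch) on the
#' lag-strided discrete trajectories and initialised from the PCCA+
#' memberships. Convergence requires the log-likelihood gain to fall
#' below `tol`; non-convergence within `max_iter` iterations is an
#' error carrying the tail of the likelihood trace. Hidden states are
#' canonically ordered by their mean observed feature value so that
#' state labels are reproducible.
#'
#' @param dtrajs Microstate trajectory (or list), states 1..S.
#' @param n_hidden Number of hidden states (default 3).
#' @param lag Lag in frames; the EM runs on every lag-th frame (all
#'   offsets contribute as separate sequences).
#' @param init Optional S x n_hidden membership initialisation (from
#'   [pcca_coarse()]); computed internally when NULL.
#' @param obs_centers Optional feature value per microstate, used for
#'   canonical ordering.
#' @param seed Seed (kept for interface stability; the EM itself is
#'   deterministic given its initialisation).
#' @param tol Relative log-likelihood gain threshold (default 1e-8;
#'   applied to the gain divided by the likelihood magnitude).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return List of class `hmm_model`: `T_coarse`, `populations`,
#'   `observation` (n_hidden x S), `loglik`, `n_iter`, `lag`.
#' @export
hmm_refine <- function(dtrajs, n_hidden = 3, lag = 1, init = NULL,
                       obs_centers = NULL, seed = 7, tol = 1e-8,
                       max_iter = 1000) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  ## alphabet size from the centers when given, so resamples that miss
  ## the extreme bins keep a consistent observation matrix
  S <- max(unlist(lapply(dtrajs, max)),
           if (!is.null(obs_centers)) length(obs_centers) else 0L)
  ## lag-strided observation sequences, 0-based symbols for the C++ core
  seqs <- list()
  for (d in dtrajs) {
    for (off in seq_len(lag)) {
      s <- d[seq(off, length(d), by = lag)]
      if (length(s) >= 2) seqs[[length(seqs) + 1L]] <- as.integer(s - 1L)
    }
  }
  if (!length(seqs)) stop("no usable sequences at this lag")
  if (is.null(init)) {
    m <- estimate_msm(dtrajs, lag)
    chi_act <- pcca_coarse(m$T, n_hidden)
    chi <- matrix(1 / n_hidden, S, n_hidden)
    chi[m$active, ] <- chi_act
    pi_micro <- rep(1e-8, S)
    pi_micro[m$active] <- m$pi
    A0 <- coarse_grain_T(m$T, m$pi, chi_act)
  } else {
    chi <- init
    pi_micro <- rep(1 / S, S)
    A0 <- matrix(1 / n_hidden, n_hidden, n_hidden)
    diag(A0) <- 1
    A0 <- A0 / rowSums(A0)
  }
  B <- t(chi * pi_micro)
  B <- B + 1e-12
  B <- B / rowSums(B)
  A <- pmax(A0, 1e-12)
  A <- A / rowSums(A)
  p0 <- rep(1 / n_hidden, n_hidden)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    est <- hmm_estep(seqs, A, B, p0)
    trace <- c(trace, est$loglik)
    ## gain threshold scaled by the likelihood magnitude, so long
    ## sequences (|loglik| ~ 1e5) converge in bounded iterations
    thr <- tol * max(1, abs(est$loglik))
    if (it > 1 && (est$loglik - trace[it - 1]) < thr &&
        est$loglik >= trace[it - 1] - 1e-6) {
      converged <- TRUE
      break
    }
    A <- est$xi + 1e-300
    A <- A / rowSums(A)
    B <- est$gamma_symbol + 1e-300
    B <- B / rowSums(B)
    p0 <- est$gamma_init + 1e-300
    p0 <- p0 / sum(p0)
  }
  if (!converged)
    stop("EM did not converge in ", max_iter, " iterations; ",
         "last log-likelihood gains: ",
         paste(signif(diff(utils::tail(trace, 6)), 3), collapse = ", "))
  ## canonical ordering by mean observed feature (falls back to the
  ## observation-weighted mean symbol index)
  centers <- if (is.null(obs_centers)) seq_len(S) else obs_centers
  mean_feat <- drop(B %*% centers)
  ord <- order(mean_feat)
  A <- A[ord, ord, drop = FALSE]
  B <- B[ord, , drop = FALSE]
  pops <- stationary_distribution(A)
  structure(list(T_coarse = A, populations = pops, observation = B,
                 loglik = trace, n_iter = length(trace), lag = lag,
                 mean_feature = mean_feat[ord]),
            class = "hmm_model")
}

#' Transition rates from a coarse-grained transition matrix
#'
#' First-order rates at the working lag: k_ij = T_ij(tau) / tau for
#' i != j, reported in 1e-3 ns^-1.
#'
#' @param T_coarse Row-stochastic coarse transition matrix.
#' @param lag_ns Lag time in ns.
#' @return Matrix of rates (1e-3 ns^-1) with NA on the diagonal.
#' @export
#' @examples
#' transition_rates(matrix(c(0.85, 0.15, 0.1, 0.9), 2, byrow = TRUE), 15)
transition_rates <- function(T_coarse, lag_ns) {
  if (any(abs(rowSums(T_coarse) - 1) > 1e-8))
    stop("T_coarse must be row-stochastic")
  k <- T_coarse / lag_ns * 1e3
  diag(k) <- NA_real_
  k
}

#' Bootstrap uncertainties for coarse-grained transition rates
#'
#' Resamples whole trajectories with replacement, refits the full chain
#' (microstate MSM, PCCA+ initialisation, HMM refinement, rates) on
#' each resample, and reports the per-element standard deviation.
#'
#' @param dtrajs List of >= 2 microstate trajectories.
#' @param lag Lag in frames.
#' @param dt_ns Time per frame, ns.
#' @param n_hidden Number of metastable states (default 3).
#' @param n_boot Number of bootstrap resamples (default 5).
#' @param obs_centers Feature value per microstate (canonical
#'   ordering).
#' @param seed RNG seed for the resampling.
#' @return List with `rates` (point estimate on the full data),
#'   `rate_sd` (bootstrap SDs), and `boot` (per-resample rate
#'   matrices).
#' @export
bootstrap_rates <- function(dtrajs, lag, dt_ns, n_hidden = 3, n_boot = 5,
                            obs_centers = NULL, seed = 7) {
  if (!is.list(dtrajs) || length(dtrajs) < 2)
    stop("bootstrap needs at least 2 trajectories")
  hm <- hmm_refine(dtrajs, n_hidden = n_hidden, lag = lag,
                   obs_centers = obs_centers)
  point <- transition_rates(hm$T_coarse, lag * dt_ns)
  boots <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      pick <- sample.int(length(dtrajs), replace = TRUE)
      hb <- hmm_refine(dtrajs[pick], n_hidden = n_hidden, lag = lag,
                       obs_centers = obs_centers)
      transition_rates(hb$T_coarse, lag * dt_ns)
    })
  })
  arr <- simplify2array(boots)
  sds <- apply(arr, c(1, 2), stats::sd)
  diag(sds) <- NA_real_
  list(rates = point, rate_sd = sds, boot = boots)
}
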