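## Regional solvent-dynamics estimators: shell residence times (survival
## correlation and first-exit histogram), local diffusion coefficients
## from mean-square displacements, hydrogen-bond lifetime
## autocorrelation, P2 reorientation times, and block-averaged 95%
## confidence intervals.

#' Correlation curve container
#'
#' @param lags Lag times (ps), starting at 0 and strictly increasing.
#' @param values Correlation values (values[1] = 1 for normalised
#'   curves).
#' @param kind "survival", "hbond" or "p2".
#' @param n_origins Number of time origins contributing per lag.
#' @return Object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, values, kind = c("survival", "hbond",
                                                     "p2"),
                              n_origins = NULL) {
  kind <- match.arg(kind)
  if (lags[1] != 0 || any(diff(lags) <= 0))
    stop("lags must start at 0 and be strictly increasing")
  if (length(values) != length(lags)) stop("lags/values length mismatch")
  structure(list(lags = lags, values = values, kind = kind,
                 n_origins = n_origins), class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("<correlation_curve> kind=", x$kind, ", ", length(x$lags),
      " lags up to ", max(x$lags), " ps\n", sep = "")
  invisible(x)
}

#' 1/e crossing time of a correlation curve
#'
#' Linear interpolation between the bracketing samples; no functional
#' fitting. When the curve never reaches 1/e within the available lags
#' the result is flagged as a lower bound (censored).
#'
#' @param curve A `correlation_curve` (or list with `lags`, `values`).
#' @param level Crossing level, default `exp(-1)`.
#' @return List with `tau` (ps; the largest lag when censored) and
#'   `censored` (logical).
#' @export
one_over_e_time <- function(curve, level = exp(-1)) {
  lags <- curve$lags; v <- curve$values
  below <- which(v <= level)
  if (length(below) == 0L)
    return(list(tau = max(lags), censored = TRUE))
  i <- below[1]
  if (i == 1L) return(list(tau = lags[1], censored = FALSE))
  frac <- (v[i - 1] - level) / (v[i - 1] - v[i])
  list(tau = lags[i - 1] + frac * (lags[i] - lags[i - 1]), censored = FALSE)
}

#' Shell residence time from the survival correlation and by
#' first-exit histogramming
#'
#' The survival correlation C_res(t) is the probability that a molecule
#' inside the shell at a time origin is still continuously inside a lag
#' t later (first-exit convention, the default: the occupancy indicator
#' is absorbing, so the curve is monotone non-increasing and C_res(0) =
#' 1). The correlation residence time `tau_corr` is the 1/e crossing by
#' linear interpolation; the histogram residence time `tau_hist` is the
#' mean first-exit time over all (molecule, entry) episodes, excluding
#' episodes censored by the end of the series. With
#' `allow_reentry = TRUE` the literal product form <h(t) h(0)> is used
#' instead and molecules may return.
#'
#' @param shell A `shell_series`.
#' @param max_lag Largest lag, ps (default: half the span).
#' @param allow_reentry Use the re-entry-tolerant product correlation.
#' @param origin_stride Use every `origin_stride`-th frame as origin.
#' @return List with `curve` (a `correlation_curve`), `tau_corr`,
#'   `tau_hist` (ps), `censored` flags and `n_episodes`.
#' @export
survival_residence <- function(shell, max_lag = NULL, allow_reentry = FALSE,
                               origin_stride = 1) {
  member <- shell$member
  dt <- shell$dt
  F <- nrow(member)
  if (F < 2L) stop("shell series needs at least 2 frames")
  if (is.null(max_lag)) max_lag <- floor((F - 1) / 2) * dt
  kmax <- floor(max_lag / dt)
  if (kmax >= F) stop("max_lag exceeds the trajectory span")
  origins <- seq(1L, F - kmax, by = origin_stride)

  if (!allow_reentry) {
    ## L[f, m] = length (frames) of the contiguous inside-run starting at f
    L <- matrix(0L, F, ncol(member))
    L[F, ] <- as.integer(member[F, ])
    for (f in (F - 1L):1L) L[f, ] <- ifelse(member[f, ], 1L + L[f + 1L, ], 0L)
    Lo <- L[origins, , drop = FALSE]
    ## survival via the run-length histogram: #(Lo > k) = #(Lo >= k+1)
    tab <- tabulate(Lo[Lo > 0L], nbins = F)
    surv <- rev(cumsum(rev(tab)))
    if (surv[1] == 0L) stop("no molecule is ever inside the shell")
    vals <- surv[1:(kmax + 1L)] / surv[1]
  } else {
    h <- member[origins, , drop = FALSE]
    n0 <- sum(h)
    if (n0 == 0L) stop("no molecule is ever inside the shell")
    vals <- vapply(0:kmax, function(k) {
      sum(member[origins + k, , drop = FALSE] & h) / n0
    }, 0)
  }
  curve <- correlation_curve((0:kmax) * dt, vals, kind = "survival",
                             n_origins = rep(length(origins), kmax + 1L))
  cr <- one_over_e_time(curve)

  ## histogram estimator: episodes are maximal inside-runs; runs touching
  ## the final frame are censored and dropped. An episode of L inside
  ## frames exits somewhere in the frame interval ((L-1) dt, L dt]; the
  ## midpoint assignment (L - 1/2) dt removes the O(dt) interval-
  ## censoring bias of the naive L dt convention.
  rl <- apply(member, 2, function(col) {
    r <- rle(col)
    len <- r$lengths[r$values]
    ends <- cumsum(r$lengths)[r$values]
    len[ends < F]
  })
  lens <- unlist(rl)
  tau_hist <- if (length(lens)) mean(lens - 0.5) * dt else NA_real_
  hist_censored <- length(lens) == 0L

  list(curve = curve,
       tau_corr = cr$tau, corr_censored = cr$censored,
       tau_hist = tau_hist, hist_censored = hist_censored,
       n_episodes = length(lens))
}

#' Local diffusion coefficient from mean-square displacements
#'
#' MSD over multiple time origins, averaged over the molecules that are
#' shell members at the time origin (or over all solvent molecules when
#' `members = NULL`). Membership is evaluated at the origin only;
#' molecules are tracked through unwrapped coordinates for the full lag
#' window even if they exit, which avoids survivorship bias toward slow
#' molecules. D is the least-squares slope over `fit_window` divided by
#' 2 * alpha with alpha = 3 dimensions.
#'
#' @param traj A `solv_trajectory`.
#' @param members Optional `shell_series` restricting origins.
#' @param fit_window c(t_min, t_max) in ps for the linear fit (default
#'   2--10 ps).
#' @param origin_stride Origin spacing in frames (default 1, i.e. every
#'   frame whose full window fits).
#' @param site_rule Solvent reference-site rules.
#' @param sites Optional precomputed frames x molecules x 3 site array
#'   (bypasses `site_rule`).
#' @return List with `D` (1e-5 cm^2/s), `D_nm2ps`, `msd` (lags ps,
#'   values nm^2), the fit, and a `flagged` field set for a negative
#'   fitted slope.
#' @export
diffusion_coefficient <- function(traj, members = NULL,
                                  fit_window = c(2, 10), origin_stride = 1,
                                  site_rule = default_site_rules(),
                                  sites = NULL) {
  dt <- traj$dt
  if (is.null(sites)) sites <- solvent_reference_site(traj, site_rule)$sites
  nf <- dim(sites)[1]; nmol <- dim(sites)[2]
  if (nmol < 2) stop("need at least 2 molecules for an MSD average")
  kmax <- floor(fit_window[2] / dt)
  if (kmax >= nf) stop("fit window exceeds available lags")
  kfit <- which((0:kmax) * dt >= fit_window[1] & (0:kmax) * dt <= fit_window[2])
  if (length(kfit) < 5) stop("fewer than 5 lag points in the fit window")
  unw <- unwrap_coords(sites, traj$box)
  origins <- seq(1L, nf - kmax, by = origin_stride)
  memo <- if (is.null(members)) matrix(TRUE, length(origins), nmol) else
    members$member[origins, , drop = FALSE]
  wsum <- sum(memo)
  if (wsum == 0) stop("no shell members at any time origin")
  msd <- numeric(kmax + 1L)
  for (k in 1:kmax) {
    d2 <- (unw[origins + k, , 1] - unw[origins, , 1])^2 +
      (unw[origins + k, , 2] - unw[origins, , 2])^2 +
      (unw[origins + k, , 3] - unw[origins, , 3])^2
    msd[k + 1L] <- sum(d2 * memo) / wsum
  }
  lags <- (0:kmax) * dt
  fit <- stats::lm.fit(cbind(1, lags[kfit]), msd[kfit])
  slope <- fit$coefficients[2]
  D_nm2ps <- unname(slope / 6)
  list(D = diffusion_nm2ps_to_report(D_nm2ps), D_nm2ps = D_nm2ps,
       msd = list(lags = lags, values = msd),
       fit = list(slope = unname(slope),
                  intercept = unname(fit$coefficients[1]),
                  window = fit_window),
       flagged = slope < 0)
}

#' Autocorrelation of binary (hydrogen-bond style) indicator series
#'
#' Intermittent correlation C(t) = <h(0) h(t)> / <h> averaged over pairs
#' and time origins, or the mean-subtracted fluctuation correlation
#' (which decays from 1 to 0 and is the natural choice when the
#' stationary occupancy is large).
#'
#' @param series frames x pairs logical/0-1 matrix.
#' @param dt Frame spacing, ps.
#' @param max_lag Largest lag, ps.
#' @param normalize "intermittent" or "fluctuation".
#' @return A `correlation_curve` of kind "hbond".
#' @export
hb_corr <- function(series, dt, max_lag = NULL,
                    normalize = c("intermittent", "fluctuation")) {
  normalize <- match.arg(normalize)
  h <- as.matrix(series) * 1
  F <- nrow(h)
  if (is.null(max_lag)) max_lag <- floor((F - 1) / 2) * dt
  kmax <- min(floor(max_lag / dt), F - 1L)
  hbar <- mean(h)
  if (hbar == 0) stop("series never on; no hydrogen bonds to correlate")
  raw <- vapply(0:kmax, function(k) {
    mean(h[seq_len(F - k), , drop = FALSE] *
           h[seq_len(F - k) + k, , drop = FALSE])
  }, 0)
  vals <- switch(normalize,
                 intermittent = raw / hbar,
                 fluctuation = {
                   v <- raw[1] - hbar^2
                   if (v <= 0) stop("series has zero variance")
                   (raw - hbar^2) / v
                 })
  correlation_curve((0:kmax) * dt, vals, kind = "hbond",
                    n_origins = (F - 0:kmax) * ncol(h))
}

#' Protein--solvent hydrogen-bond lifetime
#'
#' Builds the per-pair hydrogen-bond indicator from the geometric
#' criterion r(donor--acceptor) <= `r_cut` and angle(H--donor--acceptor)
#' <= `angle_cut`, computes the intermittent autocorrelation averaged
#' over pairs, and reports the 1/e crossing as the lifetime. Systems
#' with no donor--acceptor pairs (apolar solvents) return a
#' not-applicable result; a correlation that never decays to 1/e within
#' `max_lag` is flagged as a lower bound.
#'
#' @param traj A `solv_trajectory`.
#' @param donors Two-column matrix of atom rows `(donor, hydrogen)`.
#' @param acceptors Vector of acceptor atom rows.
#' @param max_lag Largest lag, ps.
#' @param r_cut Donor--acceptor distance cutoff, nm (default 0.35).
#' @param angle_cut H--donor--acceptor angle cutoff, degrees (default
#'   30).
#' @return List with `hblt` (ps or NA), `censored`,
#'   `not_applicable`, and the `curve`.
#' @export
hb_lifetime <- function(traj, donors, acceptors, max_lag = NULL,
                        r_cut = 0.35, angle_cut = 30) {
  if (is.null(donors) || is.null(acceptors) ||
      NROW(donors) == 0L || length(acceptors) == 0L) {
    return(list(hblt = NA_real_, censored = FALSE, not_applicable = TRUE,
                curve = NULL))
  }
  donors <- matrix(donors, ncol = 2)
  nf <- n_frames(traj)
  npair <- nrow(donors) * length(acceptors)
  h <- matrix(FALSE, nf, npair)
  cosmax <- cos(angle_cut * pi / 180)
  for (f in seq_len(nf)) {
    box <- traj$box[f, ]
    col <- 0L
    for (i in seq_len(nrow(donors))) {
      dpos <- traj$coords[f, donors[i, 1], ]
      hpos <- traj$coords[f, donors[i, 2], ]
      u_dh <- min_image_displacement(dpos, hpos, box)
      u_dh <- u_dh / sqrt(sum(u_dh^2))
      for (a in acceptors) {
        col <- col + 1L
        v_da <- min_image_displacement(dpos, traj$coords[f, a, ], box)
        r <- sqrt(sum(v_da^2))
        if (r <= r_cut && sum(u_dh * v_da) / r >= cosmax)
          h[f, col] <- TRUE
      }
    }
  }
  if (!any(h)) {
    return(list(hblt = NA_real_, censored = FALSE, not_applicable = TRUE,
                curve = NULL))
  }
  curve <- hb_corr(h, traj$dt, max_lag, normalize = "intermittent")
  cr <- one_over_e_time(curve)
  list(hblt = cr$tau, censored = cr$censored, not_applicable = FALSE,
       curve = curve)
}

#' Second-rank reorientation time of molecular unit vectors
#'
#' C2(t) = <P2(u(0) . u(t))> averaged over molecules and origins, with
#' P2(x) = (3 x^2 - 1) / 2; tau2 is the 1/e crossing. For isotropic
#' rotational diffusion with coefficient D_r, tau2 = 1 / (6 D_r).
#'
#' @param u frames x molecules x 3 array of unit vectors.
#' @param dt Frame spacing, ps.
#' @param max_lag Largest lag, ps.
#' @return List with `tau2` (ps), `censored`, and the `curve`.
#' @export
p2_reorientation <- function(u, dt, max_lag = NULL) {
  F <- dim(u)[1]
  if (is.null(max_lag)) max_lag <- floor((F - 1) / 2) * dt
  kmax <- min(floor(max_lag / dt), F - 1L)
  vals <- vapply(0:kmax, function(k) {
    i <- seq_len(F - k)
    dotp <- u[i, , 1, drop = FALSE] * u[i + k, , 1, drop = FALSE] +
      u[i, , 2, drop = FALSE] * u[i + k, , 2, drop = FALSE] +
      u[i, , 3, drop = FALSE] * u[i + k, , 3, drop = FALSE]
    mean((3 * dotp^2 - 1) / 2)
  }, 0)
  curve <- correlation_curve((0:kmax) * dt, vals, kind = "p2")
  cr <- one_over_e_time(curve)
  list(tau2 = cr$tau, censored = cr$censored, curve = curve)
}

#' Block-averaged mean with student-t 95% confidence interval
#'
#' @param values Per-block estimates (length >= 2).
#' @return List with `mean`, `half_width` (t_{n-1,0.975} s / sqrt(n))
#'   and `n`.
#' @export
#' @examples
#' block_ci(c(0, 2)) # mean 1, half-width 12.706/sqrt(2)
block_ci <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("block averaging needs at least 2 blocks")
  hw <- stats::qt(0.975, n - 1L) * stats::sd(values) / sqrt(n)
  list(mean = mean(values), half_width = hw, n = n)
}

#' Split frames into consecutive blocks
#'
#' Helper for block averaging: index vectors of (near-)equal consecutive
#' frame blocks.
#'
#' @param n_frames Total frames.
#' @param n_blocks Number of blocks (>= 2).
#' @return List of integer index vectors.
#' @export
frame_blocks <- function(n_frames, n_blocks) {
  if (n_blocks < 2) stop("need at least 2 blocks")
  cuts <- floor(seq(0, n_frames, length.out = n_blocks + 1))
  lapply(seq_len(n_blocks), function(b) (cuts[b] + 1L):cuts[b + 1L])
}
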