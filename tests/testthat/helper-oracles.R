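## Independent brute-force oracles used to validate the optimised
## implementations, plus small fixture builders. Oracles deliberately
## use the dumbest correct algorithm.

## minimum image by explicit search over the 27 periodic images
bf_min_image <- function(a, b, box) {
  best <- NULL; bestn <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- (b + c(i, j, k) * box) - a
    n <- sum(d^2)
    if (n < bestn - 1e-15) { bestn <- n; best <- d }
  }
  best
}

## shell membership by looping every (frame, molecule, region atom)
bf_membership <- function(traj, region_rows, sites, cutoff) {
  nf <- dim(sites)[1]; nm <- dim(sites)[2]
  member <- matrix(FALSE, nf, nm)
  for (f in seq_len(nf)) for (m in seq_len(nm)) {
    for (r in region_rows) {
      d <- bf_min_image(traj$coords[f, r, ], sites[f, m, ], traj$box[f, ])
      if (sqrt(sum(d^2)) <= cutoff) { member[f, m] <- TRUE; break }
    }
  }
  member
}

## survival correlation and first-exit episodes by direct enumeration
bf_survival <- function(member, kmax) {
  F <- nrow(member)
  num <- numeric(kmax + 1); den <- 0
  for (f in seq_len(F - kmax)) for (m in seq_len(ncol(member))) {
    if (!member[f, m]) next
    den <- den + 1
    alive <- TRUE
    for (k in 0:kmax) {
      if (!member[f + k, m]) alive <- FALSE
      if (alive) num[k + 1] <- num[k + 1] + 1 else break
    }
  }
  num / den
}

## first-exit times with the midpoint (interval-censoring) convention:
## an episode of len inside frames exits in ((len-1) dt, len dt]
bf_first_exit_times <- function(member, dt) {
  F <- nrow(member)
  out <- numeric(0)
  for (m in seq_len(ncol(member))) {
    f <- 1L
    while (f <= F) {
      if (member[f, m] && (f == 1L || !member[f - 1L, m])) {
        len <- 0L
        while (f + len <= F && member[f + len, m]) len <- len + 1L
        if (f + len <= F) out <- c(out, (len - 0.5) * dt)  # uncensored only
        f <- f + len
      } else f <- f + 1L
    }
  }
  out
}

## tiny water-in-a-box GRO text (fixed-width fields)
write_tiny_gro <- function(path, coords, resname = "SOL",
                           names = c("OW", "HW1", "HW2"), box = c(2, 2, 2),
                           title = "tiny") {
  n <- nrow(coords)
  lines <- c(title, sprintf("%5d", n))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              1L, resname, names[i], i,
                              coords[i, 1], coords[i, 2], coords[i, 3]))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  path
}

## unit vectors under isotropic rotational diffusion with coefficient Dr
gen_rotational_diffusion <- function(D_r, n_mol, n_frames, dt, seed = 7) {
  set.seed(seed)
  u <- array(0, dim = c(n_frames, n_mol, 3))
  cur <- matrix(rnorm(n_mol * 3), n_mol, 3)
  cur <- cur / sqrt(rowSums(cur^2))
  u[1, , ] <- cur
  s <- sqrt(2 * D_r * dt)
  for (f in 2:n_frames) {
    xi <- matrix(rnorm(n_mol * 3, sd = s), n_mol, 3)
    xi <- xi - cur * rowSums(xi * cur)     # tangential component
    cur <- cur + xi
    cur <- cur / sqrt(rowSums(cur^2))
    u[f, , ] <- cur
  }
  u
}

## matrix exponential by scaling-and-squaring on the truncated series
## (independent of any package implementation)
bf_expm <- function(A, order = 12) {
  n <- nrow(A)
  s <- max(0, ceiling(log2(max(1e-12, norm(A, "1")))))
  As <- A / 2^s
  X <- diag(n); term <- diag(n)
  for (k in 1:order) {
    term <- term %*% As / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}
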