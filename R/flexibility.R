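## Protein flexibility: rigid-body superposition, per-residue RMSF
## (all-atom / side-chain / C-alpha variants), regional integration and
## flexibility ratios, and structural sanity checks (RMSD, radius of
## gyration).

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, NA2 = 22.990, CL = 35.45,
                  K = 39.098, X = 12.011)

atom_masses <- function(atoms) {
  m <- ELEMENT_MASS[atoms$element]
  m[atoms$element == "NA"] <- 22.990
  m[is.na(m)] <- 12.011
  unname(m)
}

## Kabsch rigid-body fit: rotation + translation carrying P onto Q
## (both n x 3, n >= 3), least squares. Returns the transform.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2) stop("degenerate (collinear) fit atoms")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, cp = cp, cq = cq)
}

apply_fit <- function(X, fit) {
  sweep(sweep(X, 2, fit$cp) %*% t(fit$R), 2, fit$cq, `+`)
}

#' Superpose a trajectory onto a reference structure
#'
#' Per-frame least-squares rigid-body fit (rotation plus translation)
#' minimising the RMSD of the fit atoms to the reference. By default the
#' fit atoms are the C-alpha set and the reference is the trajectory's
#' own time-mean structure, obtained by a first-pass fit to frame 1
#' followed by one refit to the resulting mean -- RMSF measures
#' fluctuation about the mean, so the mean is the natural reference.
#'
#' @param traj A `solv_trajectory`.
#' @param reference Optional n_atoms x 3 reference coordinates (nm); NULL
#'   for the iterated-mean procedure.
#' @param fit_rows Atom rows used for fitting; default all atoms named
#'   "CA" (>= 3 required, non-collinear).
#' @return The aligned `solv_trajectory` (periodicity is considered
#'   resolved after alignment; the box is carried unchanged).
#' @export
superpose <- function(traj, reference = NULL, fit_rows = NULL) {
  if (is.null(fit_rows)) fit_rows <- which(traj$atoms$name == "CA")
  if (length(fit_rows) < 3) stop("need at least 3 fit atoms")
  align_to <- function(ref) {
    out <- traj$coords
    for (f in seq_len(n_frames(traj))) {
      fit <- kabsch_fit(matrix(traj$coords[f, fit_rows, ], ncol = 3),
                        matrix(ref[fit_rows, ], ncol = 3))
      out[f, , ] <- apply_fit(matrix(traj$coords[f, , ], ncol = 3), fit)
    }
    out
  }
  if (is.null(reference)) {
    first <- align_to(matrix(traj$coords[1, , ], ncol = 3))
    reference <- apply(first, c(2, 3), mean)
  }
  aligned <- traj
  aligned$coords <- align_to(reference)
  aligned
}

#' Per-residue RMSF of an aligned trajectory
#'
#' Per atom, the root-mean-square deviation from its time-mean position;
#' per residue, the unweighted mean over the variant's atom set (all
#' atoms, side-chain atoms only, or C-alpha only). Residues with no
#' atoms in the variant (e.g. glycine side chains) are flagged NA. Set
#' `mass_weighted = TRUE` for a mass-weighted residue mean.
#'
#' @param traj An aligned `solv_trajectory` (>= 2 frames).
#' @param variant "all_atom", "side_chain" or "c_alpha".
#' @param mass_weighted Mass-weight the per-residue mean (default
#'   FALSE).
#' @return data.frame with `resid` and `rmsf` (nm).
#' @export
rmsf <- function(traj, variant = c("all_atom", "side_chain", "c_alpha"),
                 mass_weighted = FALSE) {
  variant <- match.arg(variant)
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  a <- traj$atoms
  prot <- a$mol_class == "protein"
  keep <- switch(variant,
                 all_atom = prot,
                 side_chain = prot & !(a$name %in% BACKBONE_NAMES),
                 c_alpha = prot & a$name == "CA")
  resids <- sort(unique(a$resid[prot]))
  mean_pos <- apply(traj$coords, c(2, 3), mean)
  dev2 <- 0
  for (k in 1:3) {
    d <- sweep(traj$coords[, , k], 2, mean_pos[, k])
    dev2 <- dev2 + colMeans(d^2)
  }
  atom_rmsf <- sqrt(dev2)
  w <- if (mass_weighted) atom_masses(a) else rep(1, nrow(a))
  out <- vapply(resids, function(rs) {
    rows <- which(keep & a$resid == rs)
    if (!length(rows)) return(NA_real_)
    sum(atom_rmsf[rows] * w[rows]) / sum(w[rows])
  }, 0)
  data.frame(resid = resids, rmsf = out)
}

#' Integrated regional RMSF
#'
#' The region's flexibility score: the sum of per-residue RMSF over the
#' region's residues (a rectangle rule in residue index).
#'
#' @param rmsf_profile data.frame from [rmsf()] (`resid`, `rmsf`).
#' @param region A `region_spec`.
#' @return Integrated RMSF, nm.
#' @export
regional_flexibility <- function(rmsf_profile, region) {
  want <- region_residues(region)
  miss <- setdiff(want, rmsf_profile$resid)
  if (length(miss))
    stop("region '", region$name, "' residues absent from profile: ",
         paste(utils::head(miss, 5), collapse = ", "))
  vals <- rmsf_profile$rmsf[match(want, rmsf_profile$resid)]
  sum(vals, na.rm = TRUE)
}

#' Flexibility ratio relative to the aqueous run
#'
#' @param value_solvent Integrated regional RMSF in the solvent of
#'   interest.
#' @param value_water Integrated regional RMSF of the same region in
#'   water (nonzero).
#' @return Dimensionless ratio (1 for the water run by construction).
#' @export
flexibility_ratio <- function(value_solvent, value_water) {
  if (any(value_water == 0)) stop("water reference value must be nonzero")
  value_solvent / value_water
}

#' Structural sanity checks: RMSD and radius of gyration time series
#'
#' Per-frame C-alpha RMSD to the reference after superposition, and the
#' mass-weighted radius of gyration of the protein per frame.
#'
#' @param traj A `solv_trajectory`.
#' @param reference n_atoms x 3 reference coordinates (nm), matching the
#'   trajectory's atom set.
#' @return data.frame with `time` (ps), `rmsd` (nm) and `rg` (nm).
#' @export
structure_checks <- function(traj, reference) {
  reference <- as.matrix(reference)
  if (nrow(reference) != n_atoms(traj))
    stop("reference has ", nrow(reference), " atoms but trajectory has ",
         n_atoms(traj))
  ca <- which(traj$atoms$name == "CA")
  if (length(ca) < 3) ca <- which(traj$atoms$mol_class == "protein")
  aligned <- if (length(ca) >= 3)
    superpose(traj, reference = reference, fit_rows = ca)
  else traj   # too few atoms for a rigid fit; compare in place
  prot <- which(traj$atoms$mol_class == "protein")
  m <- atom_masses(traj$atoms)[prot]
  nf <- n_frames(traj)
  rmsd <- numeric(nf); rg <- numeric(nf)
  for (f in seq_len(nf)) {
    d <- matrix(aligned$coords[f, ca, ], ncol = 3) -
      matrix(reference[ca, ], ncol = 3)
    rmsd[f] <- sqrt(mean(rowSums(d^2)))
    X <- matrix(traj$coords[f, prot, ], ncol = 3)
    com <- colSums(X * m) / sum(m)
    rg[f] <- sqrt(sum(m * rowSums(sweep(X, 2, com)^2)) / sum(m))
  }
  data.frame(time = frame_times(traj), rmsd = rmsd, rg = rg)
}
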