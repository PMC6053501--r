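## First solvation shell definition: per-molecule solvent reference
## sites, proximal radial distribution functions around a region,
## first-minimum cutoff detection, and per-frame shell membership.

#' Shell membership series constructor
#'
#' @param member frames x molecules logical matrix.
#' @param dt Frame spacing, ps.
#' @param region Region name (optional).
#' @param cutoff_nm Cutoff used (optional).
#' @param solvent_site Description of the reference-site rule used.
#' @return Object of class `shell_series`.
#' @export
shell_series <- function(member, dt, region = NULL, cutoff_nm = NA_real_,
                         solvent_site = NA_character_) {
  member <- as.matrix(member)
  storage.mode(member) <- "logical"
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  structure(list(member = member, dt = dt, region = region,
                 cutoff_nm = cutoff_nm, solvent_site = solvent_site),
            class = "shell_series")
}

#' @export
print.shell_series <- function(x, ...) {
  cat("<shell_series> ", nrow(x$member), " frames x ", ncol(x$member),
      " molecules", if (!is.null(x$region)) paste0(", region ", x$region),
      if (!is.na(x$cutoff_nm)) paste0(", cutoff ", x$cutoff_nm, " nm"),
      "\n  mean occupancy ", signif(mean(x$member), 4), "\n", sep = "")
  invisible(x)
}

#' Default solvent reference-site rules
#'
#' Distances to the shell are measured from one reference site per
#' solvent molecule: the water oxygen, the nitrile nitrogen for
#' acetonitrile, the hydroxyl oxygen for alcohols; species with no rule
#' fall back to the molecule's centre of geometry (e.g. cyclohexane).
#'
#' @return Named list mapping resname to a character vector of candidate
#'   atom names, or the string "cog".
#' @export
default_site_rules <- function() {
  list(SOL = c("OW", "O"), HOH = c("OW", "O"), WAT = c("OW", "O"),
       TIP3 = c("OW", "OH2", "O"), SPC = c("OW", "O"),
       ACN = c("N", "N1", "NC"), MCN = c("N", "N1", "NC"),
       BUT = c("O", "OH", "O1"), NBU = c("O", "OH", "O1"),
       TBU = c("O", "OH", "O1"),
       CHX = "cog", CYH = "cog", SLV = "cog")
}

solvent_molecules <- function(traj) {
  a <- traj$atoms
  ids <- unique(a$mol_id[a$mol_class == "solvent"])
  if (length(ids) == 0L) stop("trajectory contains no solvent molecules")
  lapply(ids, function(id) which(a$mol_id == id))
}

#' Per-frame solvent reference-site positions
#'
#' @param traj A `solv_trajectory`.
#' @param rule Site rules as in [default_site_rules()]; molecules whose
#'   resname has no entry use their centre of geometry.
#' @return List with `sites` (frames x molecules x 3 array, nm) and
#'   `mol_rows` (atom rows per molecule).
#' @export
solvent_reference_site <- function(traj, rule = default_site_rules()) {
  mols <- solvent_molecules(traj)
  nf <- n_frames(traj)
  nm <- length(mols)
  sites <- array(NA_real_, dim = c(nf, nm, 3))
  a <- traj$atoms
  for (m in seq_len(nm)) {
    rows <- mols[[m]]
    resn <- a$resname[rows[1]]
    spec <- rule[[resn]]
    if (is.null(spec) || identical(spec, "cog")) {
      if (length(rows) == 1L) {
        sites[, m, ] <- traj$coords[, rows, ]
      } else {
        ## centre of geometry with the molecule re-imaged about atom 1
        ref <- traj$coords[, rows[1], , drop = FALSE]
        acc <- array(0, dim = c(nf, 1, 3))
        for (r in rows) {
          for (k in 1:3) {
            d <- traj$coords[, r, k] - ref[, 1, k]
            L <- traj$box[, k]
            acc[, 1, k] <- acc[, 1, k] + d - L * round(d / L)
          }
        }
        sites[, m, ] <- ref[, 1, ] + acc[, 1, ] / length(rows)
      }
    } else {
      hit <- rows[match(spec, a$name[rows])]
      hit <- hit[!is.na(hit)][1]
      if (is.na(hit))
        stop("reference atom ", paste(spec, collapse = "/"),
             " absent from molecule of residue ", resn)
      sites[, m, ] <- traj$coords[, hit, ]
    }
  }
  list(sites = sites, mol_rows = mols)
}

## Nearest min-image distance from each site to any region atom, one
## frame at a time. sites: M x 3; ratoms: K x 3; box: length 3.
nearest_region_distance <- function(sites, ratoms, box) {
  M <- nrow(sites); K <- nrow(ratoms)
  best <- rep(Inf, M)
  for (j in seq_len(K)) {
    d2 <- 0
    for (k in 1:3) {
      d <- sites[, k] - ratoms[j, k]
      d <- d - box[k] * round(d / box[k])
      d2 <- d2 + d * d
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Proximal radial distribution function around a region
#'
#' Histogram of the nearest-region-atom distance for each solvent
#' reference site, normalised so that g(r) -> 1 at large r. Because the
#' "shells" of the nearest-distance field around an irregular atom
#' cluster are not spherical, their volumes are estimated by Monte-Carlo
#' insertion (`proximal_mc`, the default); the alternative `plateau`
#' normalisation divides the count density by its mean over the
#' outermost 20\% of r bins.
#'
#' @param traj A `solv_trajectory`.
#' @param region A `region_spec`.
#' @param r_max Histogram range, nm.
#' @param dr Bin width, nm.
#' @param atom_scope "all" or "side_chain" region atoms.
#' @param normalization "proximal_mc" or "plateau".
#' @param site_rule Solvent reference-site rules.
#' @param frame_stride Analyse every `frame_stride`-th frame.
#' @param n_insert Monte-Carlo insertion points per analysed frame.
#' @param seed Seed for the insertion sampler.
#' @return Object of class `rdf_profile`: `r_centers`, `g`,
#'   `raw_counts`, `normalization`, `dr`.
#' @export
regional_rdf <- function(traj, region, r_max = 1.5, dr = 0.02,
                         atom_scope = c("all", "side_chain"),
                         normalization = c("proximal_mc", "plateau"),
                         site_rule = default_site_rules(),
                         frame_stride = 1, n_insert = 1e5, seed = 7) {
  atom_scope <- match.arg(atom_scope)
  normalization <- match.arg(normalization)
  if (!(r_max > dr && dr > 0)) stop("need r_max > dr > 0")
  rows <- region_atom_rows(traj, region, atom_scope)
  ss <- solvent_reference_site(traj, site_rule)
  frames <- seq(1, n_frames(traj), by = frame_stride)
  breaks <- seq(0, r_max, by = dr)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  vol_frac <- numeric(nb)
  with_seed(seed, {
    for (f in frames) {
      ratoms <- matrix(traj$coords[f, rows, ], ncol = 3)
      d <- nearest_region_distance(ss$sites[f, , , drop = TRUE] |>
                                     matrix(ncol = 3), ratoms, traj$box[f, ])
      counts <- counts + tabulate(findInterval(d[d < r_max], breaks,
                                               rightmost.closed = TRUE), nb)
      ## MC estimate of the nearest-distance shell volumes
      pts <- cbind(runif(n_insert, 0, traj$box[f, 1]),
                   runif(n_insert, 0, traj$box[f, 2]),
                   runif(n_insert, 0, traj$box[f, 3]))
      dmc <- nearest_region_distance(pts, ratoms, traj$box[f, ])
      vol_frac <- vol_frac +
        tabulate(findInterval(dmc[dmc < r_max], breaks,
                              rightmost.closed = TRUE), nb) / n_insert
    }
  })
  nfr <- length(frames)
  vbox <- mean(apply(traj$box[frames, , drop = FALSE], 1, prod))
  shell_vol <- vol_frac / nfr * vbox            # nm^3 per bin (averaged)
  nmol <- dim(ss$sites)[2]
  rho_bulk <- nmol / vbox
  dens <- counts / nfr / pmax(shell_vol, .Machine$double.eps)
  g <- switch(normalization,
              proximal_mc = dens / rho_bulk,
              plateau = {
                outer_bins <- seq.int(ceiling(0.8 * nb) + 1L, nb)
                ref <- mean(dens[outer_bins][shell_vol[outer_bins] > 0])
                dens / ref
              })
  g[shell_vol == 0] <- NA_real_
  structure(list(r_centers = breaks[-1] - dr / 2, g = g,
                 raw_counts = counts, normalization = normalization,
                 dr = dr, n_frames = nfr, n_molecules = nmol),
            class = "rdf_profile")
}

#' First-shell cutoff from an RDF profile
#'
#' Locates the first local minimum after the first local maximum of the
#' smoothed g(r); this radius bounds the first solvation shell. The bin
#' width is returned as the uncertainty. Structureless profiles (no
#' interior maximum followed by a minimum) raise a "no shell structure"
#' error; use [shell_cutoff_default()] when detection is skipped.
#'
#' @param rdf An `rdf_profile` (>= 10 bins).
#' @param smoothing_window Centred moving-average window in bins
#'   (default 3); ties are broken toward smaller r.
#' @return List with `cutoff_nm` and `uncertainty_nm`.
#' @export
first_shell_cutoff <- function(rdf, smoothing_window = 3) {
  g <- rdf$g
  if (length(g) < 10L) stop("rdf must have at least 10 bins")
  ok <- !is.na(g)
  r <- rdf$r_centers[ok]; g <- g[ok]
  if (smoothing_window > 1) {
    w <- rep(1 / smoothing_window, smoothing_window)
    gs <- stats::filter(g, w, sides = 2)
    gs[is.na(gs)] <- g[is.na(gs)]
    g <- as.numeric(gs)
  }
  n <- length(g)
  imax <- NA_integer_
  for (i in 2:(n - 1)) {
    if (g[i] > g[i - 1] && g[i] >= g[i + 1]) { imax <- i; break }
  }
  if (is.na(imax)) stop("no shell structure in g(r)")
  imin <- NA_integer_
  for (i in (imax + 1L):(n - 1L)) {
    if (g[i] < g[i - 1] && g[i] <= g[i + 1]) { imin <- i; break }
  }
  if (is.na(imin) || g[imin] >= g[imax]) stop("no shell structure in g(r)")
  list(cutoff_nm = r[imin], uncertainty_nm = rdf$dr)
}

#' Per-frame shell membership of solvent molecules around a region
#'
#' A molecule is a member at a frame iff the minimum-image distance from
#' its reference site to the nearest region atom is <= `cutoff_nm`.
#'
#' @param traj A `solv_trajectory`.
#' @param region A `region_spec`.
#' @param cutoff_nm Shell cutoff, nm (> 0); defaults to the region's
#'   override when present.
#' @param site_rule Solvent reference-site rules.
#' @param atom_scope Region atom scope: "all" (default) or "side_chain".
#' @return A `shell_series`.
#' @export
shell_membership <- function(traj, region, cutoff_nm = region$cutoff_nm,
                             site_rule = default_site_rules(),
                             atom_scope = c("all", "side_chain")) {
  atom_scope <- match.arg(atom_scope)
  if (is.null(cutoff_nm) || !is.numeric(cutoff_nm) || cutoff_nm <= 0)
    stop("cutoff_nm must be > 0")
  rows <- region_atom_rows(traj, region, atom_scope)
  ss <- solvent_reference_site(traj, site_rule)
  nf <- n_frames(traj)
  nm <- dim(ss$sites)[2]
  member <- matrix(FALSE, nf, nm)
  for (f in seq_len(nf)) {
    d <- nearest_region_distance(matrix(ss$sites[f, , ], ncol = 3),
                                 matrix(traj$coords[f, rows, ], ncol = 3),
                                 traj$box[f, ])
    member[f, ] <- d <= cutoff_nm
  }
  shell_series(member, dt = traj$dt, region = region$name,
               cutoff_nm = cutoff_nm,
               solvent_site = "reference-site rule")
}
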