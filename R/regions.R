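## Region specifications: named residue ranges with secondary-structure
## class and exposure labels, plus the per-solvent first-shell cutoff
## defaults.

#' Define a protein region
#'
#' A region is a named set of inclusive 1-based residue ranges with a
#' secondary-structure class and an exposure label, optionally carrying a
#' fixed first-shell cutoff that overrides detection/defaults.
#'
#' @param name Region name, e.g. "alpha5".
#' @param klass One of "helix", "sheet", "loop", "connector".
#' @param resid_ranges List of length-2 integer vectors `c(start, end)`
#'   (inclusive, 1-based), or a single such vector.
#' @param exposure "Ext", "Int" or "Int-Ext".
#' @param cutoff_nm Optional shell cutoff override (nm).
#' @return An object of class `region_spec`.
#' @export
#' @examples
#' region_spec("alpha5", "helix", c(142, 146), "Ext")
region_spec <- function(name, klass = c("helix", "sheet", "loop", "connector"),
                        resid_ranges, exposure = c("Ext", "Int", "Int-Ext"),
                        cutoff_nm = NULL) {
  klass <- match.arg(klass)
  exposure <- match.arg(exposure)
  if (!is.list(resid_ranges)) resid_ranges <- list(resid_ranges)
  if (length(resid_ranges) == 0L) stop("resid_ranges must be non-empty")
  for (r in resid_ranges) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < 1)
      stop("each residue range must be c(start, end) with 1 <= start <= end")
  }
  if (!is.null(cutoff_nm) && (!is.numeric(cutoff_nm) || cutoff_nm <= 0))
    stop("cutoff_nm override must be positive")
  structure(list(name = as.character(name), klass = klass,
                 resid_ranges = lapply(resid_ranges, as.integer),
                 exposure = exposure, cutoff_nm = cutoff_nm),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  rng <- paste(vapply(x$resid_ranges,
                      function(r) paste(r, collapse = "-"), ""),
               collapse = ", ")
  cat("<region> ", x$name, " (", x$klass, ", ", x$exposure, ") residues ",
      rng, if (!is.null(x$cutoff_nm)) paste0(", cutoff ", x$cutoff_nm, " nm"),
      "\n", sep = "")
  invisible(x)
}

#' Bundle regions into a region map
#'
#' @param ... `region_spec` objects.
#' @return Named list of regions (class `region_map`); names must be
#'   unique.
#' @export
region_map <- function(...) {
  regs <- list(...)
  if (length(regs) == 1L && is.list(regs[[1]]) &&
      !inherits(regs[[1]], "region_spec")) regs <- regs[[1]]
  stopifnot(all(vapply(regs, inherits, logical(1), "region_spec")))
  nm <- vapply(regs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("region names must be unique within a map")
  structure(setNames(regs, nm), class = "region_map")
}

#' Read a region map from a YAML file
#'
#' Expected layout: a top-level `regions:` list, each entry with fields
#' `name`, `klass`, `ranges` (list of `[start, end]`), `exposure` and
#' optional `cutoff_nm`.
#'
#' @param path YAML file.
#' @return A `region_map`.
#' @export
read_region_map <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- if (!is.null(y$regions)) y$regions else y
  region_map(lapply(entries, function(e) {
    region_spec(e$name, e$klass,
                lapply(e$ranges, function(r) as.integer(unlist(r))),
                e$exposure, cutoff_nm = e$cutoff_nm)
  }))
}

#' Residues covered by a region
#' @param region A `region_spec`.
#' @return Integer vector of residue numbers.
#' @export
region_residues <- function(region) {
  unique(unlist(lapply(region$resid_ranges, function(r) r[1]:r[2])))
}

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HA1", "HA2",
                    "H1", "H2", "H3", "HN")

#' Atom rows of a trajectory belonging to a region
#'
#' @param traj A `solv_trajectory`.
#' @param region A `region_spec`.
#' @param scope "all" for every protein atom in the region's residues,
#'   "side_chain" to exclude backbone atoms.
#' @return Integer vector of row positions into the atom table.
#' @export
region_atom_rows <- function(traj, region, scope = c("all", "side_chain")) {
  scope <- match.arg(scope)
  a <- traj$atoms
  rows <- which(a$mol_class == "protein" &
                  a$resid %in% region_residues(region))
  if (scope == "side_chain")
    rows <- rows[!(a$name[rows] %in% BACKBONE_NAMES)]
  if (length(rows) == 0L)
    stop("region '", region$name, "' matches no atoms in the topology")
  rows
}

## First-shell cutoffs (nm) by solvent: first value exterior regions,
## second the wider cutoff used for the buried helices (alpha4/6/8 style
## interior regions). Water deliberately spans two hydration layers.
SHELL_CUTOFF_TABLE <- list(
  water = c(0.5, 0.7),
  acetonitrile = c(0.5, 0.7),
  `n-butanol` = c(0.6, 0.8),
  `tert-butanol` = c(0.4, 0.6),
  cyclohexane = c(0.7, 0.9)
)

#' Default first solvation shell cutoff for a solvent
#'
#' Per-solvent first-shell boundaries (nm): acetonitrile 0.5, n-butanol
#' 0.6, tert-butanol 0.4, cyclohexane 0.7 around exterior regions, each
#' widened by 0.2 nm around interior regions; water uses 0.5 (exterior) /
#' 0.7 (interior) so that its shell spans two hydration layers while the
#' organics use the first layer only.
#'
#' @param solvent Solvent name (water, acetonitrile, n-butanol,
#'   tert-butanol, cyclohexane).
#' @param interior TRUE for buried/interior regions.
#' @return Cutoff in nm.
#' @export
#' @examples
#' shell_cutoff_default("acetonitrile")           # 0.5
#' shell_cutoff_default("cyclohexane", TRUE)      # 0.9
shell_cutoff_default <- function(solvent, interior = FALSE) {
  key <- tolower(gsub("[_ ]", "-", solvent))
  key <- switch(key, tbutanol = , "t-butanol" = "tert-butanol",
                nbutanol = , butanol = "n-butanol", key)
  row <- SHELL_CUTOFF_TABLE[[key]]
  if (is.null(row)) stop("no default shell cutoff for solvent: ", solvent)
  row[if (interior) 2L else 1L]
}
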