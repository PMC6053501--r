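## Descriptor-flexibility correlation panels: regional flexibility
## ratios against the four solvent-mobility descriptors (inverse bulk
## viscosity, solvent mobility ratio, surface retardation factor,
## inverse local viscosity), one Pearson r per panel.

DESCRIPTOR_NAMES <- c("inv_bulk_viscosity", "mobility_ratio",
                      "retardation", "inv_local_viscosity")

#' Pearson product-moment correlation coefficient
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return r in [-1, 1].
#' @export
#' @examples
#' pearson_r(1:4, c(2, 1, 4, 3)) # 0.6
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  stats::cor(x, y)
}

#' Assemble descriptor--flexibility correlation panels
#'
#' One panel per region x RMSF variant x descriptor: each point is one
#' solvent, with x the descriptor value for that (solvent, region) and y
#' the region's flexibility ratio relative to water. With
#' `include_water = TRUE` (default) water contributes its own point,
#' which has y = 1 by construction (and x = 1 exactly for the mobility
#' ratio).
#'
#' @param flexibility data.frame with columns `region`, `variant`,
#'   `solvent`, `ratio` (water rows have ratio 1).
#' @param descriptors data.frame with columns `solvent`, `region`,
#'   `D_region` (shell diffusion), `D_bulk` (model bulk diffusion),
#'   `eta_bulk` (model bulk viscosity, mPa.s). Units cancel in the
#'   ratios; viscosities are mPa.s.
#' @param regions Character vector of region names (default: all in
#'   `flexibility`).
#' @param variants RMSF variants to include (default: all present).
#' @param include_water Include the water point (default TRUE).
#' @return data.frame of panels: `region`, `variant`, `descriptor`,
#'   `r`, `n`, plus an attribute `"points"` holding the per-point table.
#' @export
build_panels <- function(flexibility, descriptors,
                         regions = unique(flexibility$region),
                         variants = unique(flexibility$variant),
                         include_water = TRUE) {
  pts <- NULL
  for (rg in regions) {
    dwat <- descriptors[descriptors$solvent == "water" &
                          descriptors$region == rg, ]
    if (nrow(dwat) != 1L)
      stop("missing water descriptor row for region ", rg)
    solvents <- union(unique(flexibility$solvent),
                      unique(descriptors$solvent))
    if (!include_water) solvents <- setdiff(solvents, "water")
    for (sv in solvents) {
      drow <- descriptors[descriptors$solvent == sv &
                            descriptors$region == rg, ]
      if (nrow(drow) != 1L)
        stop("missing descriptor row for (", sv, ", ", rg, ")")
      eta_loc <- local_viscosity(drow$eta_bulk, drow$D_bulk, drow$D_region)
      mob <- mobility_descriptors(drow$D_region, dwat$D_region,
                                  drow$D_bulk)
      xs <- c(inv_bulk_viscosity = 1 / drow$eta_bulk,
              mobility_ratio = mob$mobility_ratio,
              retardation = mob$retardation,
              inv_local_viscosity = 1 / eta_loc)
      for (vt in variants) {
        frow <- flexibility[flexibility$region == rg &
                              flexibility$variant == vt &
                              flexibility$solvent == sv, ]
        if (nrow(frow) != 1L)
          stop("missing flexibility ratio for (", rg, ", ", vt, ", ",
               sv, ")")
        pts <- rbind(pts, data.frame(
          region = rg, variant = vt, solvent = sv,
          descriptor = DESCRIPTOR_NAMES,
          x = unname(xs[DESCRIPTOR_NAMES]), y = frow$ratio,
          stringsAsFactors = FALSE))
      }
    }
  }
  panels <- do.call(rbind, lapply(
    split(pts, list(pts$region, pts$variant, pts$descriptor),
          drop = TRUE),
    function(p) data.frame(region = p$region[1], variant = p$variant[1],
                           descriptor = p$descriptor[1],
                           r = pearson_r(p$x, p$y), n = nrow(p),
                           stringsAsFactors = FALSE)))
  rownames(panels) <- NULL
  attr(panels, "points") <- pts
  panels
}
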