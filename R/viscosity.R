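## Viscosity and mobility descriptors: Stokes-Einstein utilities,
## model (bulk) viscosity, local solvation-layer viscosity (from
## diffusion ratios or tau2 ratios), the two mobility descriptors, and
## Kramers barrier-crossing rates. All descriptor arithmetic is done on
## unrounded values; rounding happens only at report time.

#' Stokes--Einstein translational and rotational diffusion
#'
#' D_T = k_B T / (6 pi eta r), D_R = k_B T / (8 pi eta r^3), evaluated
#' in SI and converted: D_T in cm^2/s, D_R in s^-1.
#'
#' @param eta Shear viscosity, mPa.s (> 0).
#' @param r Hydrodynamic radius, nm (> 0).
#' @param temperature Temperature, K (> 0).
#' @return List with `D_T_cm2s` and `D_R_per_s`.
#' @export
#' @examples
#' stokes_einstein(0.89, 1, 298)$D_T_cm2s # ~2.45e-6
stokes_einstein <- function(eta, r, temperature = 300) {
  if (eta <= 0 || r <= 0 || temperature <= 0)
    stop("eta, r and temperature must all be > 0")
  k_B <- phys_constants(temperature)$k_B
  eta_si <- eta * 1e-3      # Pa.s
  r_si <- r * 1e-9          # m
  D_T <- k_B * temperature / (6 * pi * eta_si * r_si)        # m^2/s
  D_R <- k_B * temperature / (8 * pi * eta_si * r_si^3)      # s^-1
  list(D_T_cm2s = D_T * 1e4, D_R_per_s = D_R)
}

#' Model (apparent) bulk viscosity from diffusion ratios
#'
#' In the Stokes--Einstein limit viscosity and diffusion are inversely
#' proportional at fixed radius, so a solvent model's apparent viscosity
#' is the experimental viscosity scaled by the experiment/model
#' diffusion ratio: eta_model = eta_exp * D_exp / D_model.
#'
#' @param eta_exp Experimental viscosity, mPa.s.
#' @param D_exp Experimental diffusion coefficient (any unit, shared
#'   with `D_model`).
#' @param D_model Model bulk diffusion coefficient.
#' @return Apparent model viscosity, mPa.s.
#' @export
#' @examples
#' model_viscosity(0.39, 4.04, 4.62) # acetonitrile -> 0.34 at 2 d.p.
model_viscosity <- function(eta_exp, D_exp, D_model) {
  if (any(eta_exp <= 0) || any(D_exp <= 0)) stop("inputs must be > 0")
  if (any(D_model == 0)) stop("D_model must be nonzero")
  eta_exp * D_exp / D_model
}

#' Local solvation-layer viscosity from diffusion retardation
#'
#' eta_local = eta_bulk * D_bulk / D_local: the bulk viscosity scaled by
#' how much the solvent slows down inside the shell.
#'
#' @param eta_bulk Bulk (model) viscosity, mPa.s.
#' @param D_bulk Bulk diffusion coefficient.
#' @param D_local Shell (regional) diffusion coefficient, same units.
#' @return Local viscosity, mPa.s.
#' @export
local_viscosity <- function(eta_bulk, D_bulk, D_local) {
  if (any(eta_bulk <= 0) || any(D_bulk <= 0)) stop("inputs must be > 0")
  if (any(D_local == 0)) stop("D_local must be nonzero")
  eta_bulk * D_bulk / D_local
}

#' Local viscosity from reorientation-time ratios
#'
#' The interfacial variant built on second-rank reorientation times:
#' eta_interface = eta_bulk * tau2_interface / tau2_bulk. Equivalent to
#' [local_viscosity()] whenever the Stokes--Einstein--Debye relation
#' holds (tau2 ratio equal to the inverse diffusion ratio).
#'
#' @param eta_bulk Bulk viscosity, mPa.s.
#' @param tau2_interface Interfacial reorientation time, ps.
#' @param tau2_bulk Bulk reorientation time, ps.
#' @return Interfacial viscosity, mPa.s.
#' @export
local_viscosity_from_tau2 <- function(eta_bulk, tau2_interface, tau2_bulk) {
  if (any(eta_bulk <= 0) || any(tau2_interface <= 0))
    stop("inputs must be > 0")
  if (any(tau2_bulk == 0)) stop("tau2_bulk must be nonzero")
  eta_bulk * tau2_interface / tau2_bulk
}

#' Solvent mobility ratio and surface retardation factor
#'
#' The two descriptor ratios used against regional flexibility: the
#' mobility ratio compares a solvent's shell diffusion to water's shell
#' diffusion around the same region; the retardation factor compares a
#' solvent's shell diffusion to its own bulk diffusion.
#'
#' @param D_solvent_region Shell diffusion of the solvent around the
#'   region.
#' @param D_water_region Shell diffusion of water around the same
#'   region.
#' @param D_solvent_bulk Bulk diffusion of the solvent.
#' @return List with `mobility_ratio` and `retardation`
#'   (dimensionless).
#' @export
#' @examples
#' mobility_descriptors(0.95, 1.384, 1.05)$retardation # ~0.90
mobility_descriptors <- function(D_solvent_region, D_water_region,
                                 D_solvent_bulk) {
  if (any(D_water_region == 0) || any(D_solvent_bulk == 0))
    stop("denominators must be nonzero")
  list(mobility_ratio = D_solvent_region / D_water_region,
       retardation = D_solvent_region / D_solvent_bulk)
}

#' Kramers barrier-crossing rate (high-friction limit)
#'
#' rate = prefactor * (1 / eta_local) * exp(-H_star / (R T)): inversely
#' proportional to the local viscosity and Arrhenius in the barrier.
#'
#' @param H_star Barrier height, kJ/mol.
#' @param eta_local Local viscosity, mPa.s (> 0).
#' @param temperature Temperature, K.
#' @param prefactor Proportionality constant (sets the rate units).
#' @return Rate in the prefactor's units.
#' @export
kramers_rate <- function(H_star, eta_local, temperature = 300,
                         prefactor = 1) {
  if (any(eta_local <= 0)) stop("eta_local must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  R <- phys_constants(temperature)$R
  prefactor / eta_local * exp(-H_star * 1000 / (R * temperature))
}

#' Well-to-well escape rate of a 1-D double-well series
#'
#' Counts transitions between the wells with a hysteresis rule: a
#' transition is registered when the coordinate, last seen beyond
#' -threshold, crosses +threshold (or vice versa), which is insensitive
#' to barrier-top recrossings. The rate is transitions per unit time.
#'
#' @param x Position series (well minima near +-1).
#' @param dt Time step, ps.
#' @param threshold Hysteresis threshold (default 0.7).
#' @return List with `rate` (ps^-1), `n_transitions`, `total_time`.
#' @export
escape_rate <- function(x, dt, threshold = 0.7) {
  n <- 0L
  s <- ifelse(x >= threshold, 1L, ifelse(x <= -threshold, -1L, 0L))
  s <- s[s != 0L]
  if (length(s)) {
    ch <- s[c(TRUE, diff(s) != 0L)]
    n <- length(ch) - 1L
  }
  total <- length(x) * dt
  list(rate = n / total, n_transitions = n, total_time = total)
}

## ---------------------------------------------------------------------
## Bundled reference values (worked-example inputs)

#' Bulk solvent reference values for the CALB study solvents
#'
#' Experimental viscosities and diffusion coefficients at 298 K together
#' with the simulation-model bulk diffusion coefficients for the five
#' study solvents (water and four organics). These printed reference
#' constants feed the worked-example descriptor arithmetic
#' (model/apparent viscosity, retardation factors); derived columns are
#' recomputed, never stored.
#'
#' @return data.frame with columns `solvent`, `eta_exp_mPas`,
#'   `D_exp` and `D_model` (both in 1e-5 cm^2/s).
#' @export
#' @examples
#' tab <- solvent_reference_table()
#' with(tab[tab$solvent == "acetonitrile", ],
#'      model_viscosity(eta_exp_mPas, D_exp, D_model))
solvent_reference_table <- function() {
  data.frame(
    solvent = c("water", "n-butanol", "tert-butanol", "acetonitrile",
                "cyclohexane"),
    eta_exp_mPas = c(0.89, 2.95, 3.35, 0.39, 0.98),
    D_exp = c(2.3, 0.46, 0.30, 4.04, 1.47),
    D_model = c(2.49, 0.46, 0.29, 4.62, 1.05),
    stringsAsFactors = FALSE)
}

#' Regional solvent-dynamics reference values around CALB helices
#'
#' Reference per-helix solvation-shell observables for CALB in five
#' solvents: hydrogen-bond lifetime (1/e time, ps), shell diffusion
#' coefficient (1e-5 cm^2/s) and shell residence time (ps), each with
#' its 95\% confidence half-width. Hydrogen-bond entries are NA where no
#' decaying correlation was obtained (long-lived bonds reported as "--")
#' and for the apolar solvent cyclohexane, which forms no hydrogen
#' bonds. Used as worked-example inputs for the descriptor and
#' correlation stages.
#'
#' @return Long-format data.frame: `solvent`, `helix`, `exposure`,
#'   `hblt`, `hblt_ci`, `D`, `D_ci`, `tau_res`, `tau_res_ci`.
#' @export
calb_regional_dynamics <- function() {
  helix <- paste0("alpha", 1:10)
  exposure <- c("Ext", "Int-Ext", "Int-Ext", "Int", "Ext", "Int",
                "Int-Ext", "Ext", "Int-Ext", "Ext")
  mk <- function(solvent, hblt, hblt_ci, D, D_ci, tau, tau_ci) {
    data.frame(solvent = solvent, helix = helix, exposure = exposure,
               hblt = hblt, hblt_ci = hblt_ci, D = D, D_ci = D_ci,
               tau_res = tau, tau_res_ci = tau_ci,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("water",
       c(22.6, 54.5, 63.2, 478, 25.3, 459, 20.6, 25.1, 36.8, 43.3),
       c(0.4, 5.3, 10.3, 96, 3.9, 110, 2.0, 0.5, 2.9, 2.3),
       c(1.668, 1.116, 0.986, 0.172, 1.384, 0.586, 1.258, 1.228, 1.059,
         1.454),
       c(0.029, 0.016, 0.021, 0.006, 0.044, 0.054, 0.097, 0.034, 0.022,
         0.009),
       c(45.7, 56.2, 52.6, 75.8, 42.5, 63.2, 46.1, 41.9, 59.5, 44.3),
       c(0.7, 1.4, 1.2, 4.3, 0.6, 1.6, 1.6, 0.8, 1.2, 0.3)),
    mk("n-butanol",
       c(721, 1202, 792, 1652, 422, NA, 884, 334, 1063, 746),
       c(17, 241, 78, 218, 34, NA, 42, 13, 113, 51),
       c(0.417, 0.271, 0.279, 0.167, 0.368, 0.266, 0.338, 0.369, 0.254,
         0.446),
       c(0.006, 0.004, 0.003, 0.002, 0.004, 0.005, 0.004, 0.004, 0.011,
         0.002),
       c(29.3, 23.3, 25.1, 26.3, 35.8, 31.1, 28.7, 38.7, 20.0, 34.3),
       c(1.1, 1.7, 1.0, 1.1, 1.1, 1.2, 1.4, 0.6, 0.3, 0.7)),
    mk("tert-butanol",
       c(748, 660, 705, NA, 270, NA, 177, 1475, 734, 1342),
       c(29, 49, 32, NA, 65, NA, 36, 218, 39, 182),
       c(0.223, 0.192, 0.151, 0.099, 0.180, 0.136, 0.136, 0.186, 0.123,
         0.194),
       c(0.005, 0.007, 0.007, 0.010, 0.003, 0.005, 0.006, 0.006, 0.004,
         0.005),
       c(22.3, 25.0, 29.8, 45.4, 27.2, 34.6, 33.6, 26.8, 36.3, 23.4),
       c(1.5, 3.6, 3.2, 1.8, 2.5, 1.6, 4.8, 1.6, 4.1, 0.7)),
    mk("acetonitrile",
       c(37.7, 19.5, 73.6, NA, 210, 418, 36.8, NA, 216, 63.6),
       c(0.8, 0.3, 1.3, NA, 47, 107, 0.6, NA, 19, 0.4),
       c(3.23, 2.32, 1.88, 1.68, 3.01, 1.47, 2.79, 3.04, 1.47, 3.08),
       c(0.05, 0.07, 0.06, 0.07, 0.05, 0.08, 0.06, 0.07, 0.06, 0.03),
       c(20.3, 33.6, 32.0, 37.2, 29.8, 39.2, 32.5, 29.6, 37.5, 25.0),
       c(0.5, 0.6, 0.9, 1.0, 0.6, 1.0, 1.0, 0.4, 0.4, 0.2)),
    mk("cyclohexane",
       rep(NA_real_, 10), rep(NA_real_, 10),
       c(0.76, 0.67, 0.67, 0.64, 0.95, 0.65, 0.74, 0.78, 0.64, 1.04),
       c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.01, 0.02, 0.01, 0.01),
       c(24.1, 29.4, 28.5, 38.6, 20.8, 39.2, 24.1, 23.8, 32.9, 15.8),
       c(1.0, 0.9, 0.9, 0.9, 1.0, 1.2, 0.6, 0.3, 0.5, 0.4)))
}
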