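## End-to-end orchestration from one YAML (or list) configuration:
## input acquisition, shell definition, solvent dynamics with block
## CIs, viscosity/mobility descriptors, protein flexibility, optional
## MSM stage, and a manifest recording versions, seeds and the config
## hash. Any stage failure aborts with the stage name; tables written
## before the failure are preserved.

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file path) with:
#' \describe{
#'   \item{input}{either `list(type = "fixture", ...)` passing arguments
#'     to [gen_solvated_fixture()], or `list(type = "files", topology =
#'     ..., trajectory = ...)`.}
#'   \item{solvent}{`name` plus bulk reference values `eta_bulk` (mPa.s)
#'     and `D_bulk` (1e-5 cm^2/s); optional `site_rules` overriding
#'     [default_site_rules()].}
#'   \item{regions}{region map as in [read_region_map()]; omitted for
#'     fixture input (the fixture brings its own).}
#'   \item{analysis}{optional: `n_blocks` (default 4), `fit_window`
#'     (default c(2, 10) ps), `max_lag` (ps), `cutoff_nm` override or
#'     "auto" detection flag.}
#'   \item{msm}{optional: `region_a`, `region_b`, `lag_frames`,
#'     `n_bins`, `dt_ns`.}
#'   \item{seed}{global seed (default 7).}
#'   \item{outdir}{output directory.}
#' }
#'
#' @param config List or YAML path.
#' @return The validated config (invisibly on error-free return).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$input$type))
    stop("config$input$type must be 'fixture' or 'files'")
  if (config$input$type == "files") {
    for (p in c(config$input$topology, config$input$trajectory)) {
      if (!is.null(p) && !file.exists(p)) stop("input file missing: ", p)
    }
  }
  if (is.null(config$solvent$name)) stop("config$solvent$name is required")
  rules <- config$solvent$site_rules %||% default_site_rules()
  if (config$input$type == "files") {
    ## every solvent resname in play must have a reference-site rule or
    ## explicitly fall back to centre of geometry
    known <- names(rules)
    decl <- config$solvent$resnames %||% character(0)
    miss <- setdiff(decl, known)
    if (length(miss))
      stop("no reference-site rule for solvent resname(s): ",
           paste(miss, collapse = ", "))
  }
  if (is.null(config$outdir)) stop("config$outdir is required")
  invisible(config)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full solvation-shell analysis pipeline
#'
#' Executes, in order: input acquisition (fixture generation or file
#' reading), per-region shell membership at the configured cutoffs,
#' solvent dynamics (residence times, local diffusion) with block
#' 95\% CIs, viscosity/mobility descriptors against the configured bulk
#' values, protein flexibility (per-residue RMSF, regional
#' integration), and optionally the conformational MSM stage. Tables
#' are written as CSV under `outdir` together with a JSON manifest;
#' reruns with the same config and seed produce identical numeric
#' tables.
#'
#' @param config Configuration list or YAML path (see
#'   [validate_config()]).
#' @return Invisible list of the result tables and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  seed <- config$seed %||% 7
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           if (length(written)) paste0(" (partial outputs kept: ",
                                       paste(written, collapse = ", "), ")"),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  ## -- input -----------------------------------------------------------
  inp <- stage("input", {
    if (config$input$type == "fixture") {
      args <- config$input[setdiff(names(config$input), "type")]
      args$seed <- args$seed %||% seed
      do.call(gen_solvated_fixture, args)
    } else {
      traj <- read_system(config$input$topology, config$input$trajectory,
                          dt = config$input$dt %||% 1)
      regs <- region_map(lapply(config$regions, function(e) {
        region_spec(e$name, e$klass,
                    lapply(e$ranges, function(r) as.integer(unlist(r))),
                    e$exposure, cutoff_nm = e$cutoff_nm)
      }))
      list(traj = traj, regions = regs, truth = NULL)
    }
  })
  traj <- inp$traj; regions <- inp$regions
  an <- config$analysis %||% list()
  n_blocks <- an$n_blocks %||% 4
  fit_window <- unlist(an$fit_window %||% c(2, 10))
  rules <- config$solvent$site_rules %||% default_site_rules()

  ## -- shells + solvent dynamics --------------------------------------
  dyn <- stage("dynamics", {
    sites <- solvent_reference_site(traj, rules)$sites
    rows <- NULL
    for (rg in regions) {
      cutoff <- an$cutoff_nm %||% rg$cutoff_nm %||%
        shell_cutoff_default(config$solvent$name,
                             interior = identical(rg$exposure, "Int"))
      shell <- shell_membership(traj, rg, cutoff, site_rule = rules)
      blocks <- frame_blocks(n_frames(traj), n_blocks)
      tc <- numeric(0); th <- numeric(0); dd <- numeric(0)
      frozen <- FALSE
      for (bi in blocks) {
        sub <- shell_series(shell$member[bi, , drop = FALSE], traj$dt,
                            region = rg$name, cutoff_nm = cutoff)
        sr <- try(survival_residence(sub), silent = TRUE)
        if (!inherits(sr, "try-error")) {
          if (sr$corr_censored || sr$hist_censored) frozen <- TRUE
          tc <- c(tc, sr$tau_corr); th <- c(th, sr$tau_hist)
        }
        subtraj <- traj
        subtraj$coords <- traj$coords[bi, , , drop = FALSE]
        subtraj$box <- traj$box[bi, , drop = FALSE]
        dc <- try(diffusion_coefficient(subtraj,
                                        members = sub,
                                        fit_window = fit_window,
                                        sites = sites[bi, , , drop = FALSE]),
                  silent = TRUE)
        if (!inherits(dc, "try-error")) dd <- c(dd, dc$D)
      }
      ci <- function(v) if (length(v) >= 2) block_ci(v) else
        list(mean = if (length(v)) v else NA_real_, half_width = NA_real_)
      c1 <- ci(tc); c2 <- ci(th); c3 <- ci(dd)
      rows <- rbind(rows, data.frame(
        region = rg$name, solvent = config$solvent$name,
        cutoff_nm = cutoff,
        tau_res_corr = c1$mean, tau_res_corr_ci = c1$half_width,
        tau_res_hist = c2$mean, tau_res_hist_ci = c2$half_width,
        D_local = c3$mean, D_local_ci = c3$half_width,
        residence_lower_bound = frozen,
        stringsAsFactors = FALSE))
    }
    rows
  })
  p_dyn <- file.path(outdir, "dynamics_summary.csv")
  write_table(dyn, p_dyn); written <- c(written, p_dyn)

  ## -- descriptors -----------------------------------------------------
  desc <- stage("descriptors", {
    eta_b <- config$solvent$eta_bulk
    D_b <- config$solvent$D_bulk
    if (is.null(eta_b) || is.null(D_b)) return(NULL)
    data.frame(region = dyn$region, solvent = dyn$solvent,
               eta_bulk = eta_b, D_bulk = D_b, D_local = dyn$D_local,
               eta_local = local_viscosity(eta_b, D_b, dyn$D_local),
               retardation = dyn$D_local / D_b,
               stringsAsFactors = FALSE)
  })
  if (!is.null(desc)) {
    p_desc <- file.path(outdir, "descriptors.csv")
    write_table(desc, p_desc); written <- c(written, p_desc)
  }

  ## -- flexibility -----------------------------------------------------
  flex <- stage("flexibility", {
    if (!any(traj$atoms$mol_class == "protein")) return(NULL)
    fit_rows <- which(traj$atoms$name == "CA")
    if (length(fit_rows) < 3) return(NULL)
    aligned <- superpose(traj)
    prof <- rmsf(aligned, "all_atom")
    reg_rows <- do.call(rbind, lapply(regions, function(rg) {
      data.frame(region = rg$name, variant = "all_atom",
                 integrated_rmsf = regional_flexibility(prof, rg),
                 stringsAsFactors = FALSE)
    }))
    list(profile = prof, regional = reg_rows)
  })
  if (!is.null(flex)) {
    p_prof <- file.path(outdir, "rmsf_profile.csv")
    write_table(flex$profile, p_prof); written <- c(written, p_prof)
    p_reg <- file.path(outdir, "flexibility_regional.csv")
    write_table(flex$regional, p_reg); written <- c(written, p_reg)
  }

  ## -- msm (optional) --------------------------------------------------
  msm_out <- NULL
  if (!is.null(config$msm)) {
    msm_out <- stage("msm", {
      mc <- config$msm
      feat <- min_distance_feature(traj, regions[[mc$region_a]],
                                   regions[[mc$region_b]])
      disc <- discretize_feature(feat, mc$n_bins %||% 60)
      hm <- hmm_refine(disc$dtraj, n_hidden = mc$n_meta %||% 3,
                       lag = mc$lag_frames %||% 1,
                       obs_centers = disc$centers)
      rates <- transition_rates(hm$T_coarse,
                                (mc$lag_frames %||% 1) * (mc$dt_ns %||%
                                                            traj$dt * 1e-3))
      list(rates = rates, populations = hm$populations)
    })
    p_msm <- file.path(outdir, "msm_rates.csv")
    write_table(as.data.frame(msm_out$rates), p_msm)
    written <- c(written, p_msm)
  }

  ## -- manifest --------------------------------------------------------
  manifest <- list(package = "solvshell",
                   version = as.character(utils::packageVersion("solvshell")),
                   seed = seed, config_hash = config_hash(config),
                   stage_seconds = timings,
                   outputs = written,
                   output_md5 = as.list(tools::md5sum(written)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dynamics = dyn, descriptors = desc, flexibility = flex,
                 msm = msm_out, outputs = written,
                 manifest = manifest))
}
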