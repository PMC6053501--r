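make_region_fixture <- function(n_solv = 30, n_frames = 5, box = 4,
                                D = 5e-3, seed = 13) {
  ## one 3-atom protein "region" at the box centre plus Brownian solvent
  set.seed(seed)
  b <- gen_brownian(D, n_solv, n_frames, dt = 1, box = box, seed = seed)
  prot_xyz <- rbind(c(2, 2, 2), c(2.2, 2, 2), c(2, 2.2, 2))
  atoms <- atom_table(
    name = c("CA", "CB", "CG", b$traj$atoms$name),
    resid = c(1L, 1L, 1L, b$traj$atoms$resid + 1L),
    resname = c("ALA", "ALA", "ALA", b$traj$atoms$resname),
    mol_id = c(1L, 1L, 1L, b$traj$atoms$mol_id + 1L),
    mol_class = c(rep("protein", 3), b$traj$atoms$mol_class))
  coords <- array(0, dim = c(n_frames, 3 + n_solv, 3))
  for (f in seq_len(n_frames)) coords[f, 1:3, ] <- prot_xyz
  coords[, 3 + seq_len(n_solv), ] <- b$traj$coords
  list(traj = trajectory(atoms, coords, rep(box, 3), 1),
       region = region_spec("reg", "helix", c(1, 1), "Ext"))
}

test_that("solvent reference sites follow the species rules", {
  p <- write_tiny_gro(tempfile(fileext = ".gro"),
                      rbind(c(1.0, 1.0, 1.0), c(1.06, 1.05, 1.0),
                            c(0.95, 1.07, 1.0)))
  tr <- read_system(p)
  ss <- solvent_reference_site(tr)
  expect_equal(ss$sites[1, 1, ], c(1.0, 1.0, 1.0))  # the water oxygen
  ## acetonitrile: nitrogen atom
  atoms <- atom_table(name = c("C1", "C2", "N"), resid = c(1, 1, 1),
                      resname = rep("ACN", 3), mol_id = rep(1L, 3),
                      mol_class = rep("solvent", 3),
                      element = c("C", "C", "N"))
  co <- array(0, dim = c(1, 3, 3))
  co[1, , ] <- rbind(c(1, 1, 1), c(1.1, 1, 1), c(1.2, 1, 1))
  tr2 <- trajectory(atoms, co, c(3, 3, 3), 1)
  expect_equal(solvent_reference_site(tr2)$sites[1, 1, ], c(1.2, 1, 1))
  ## unknown species falls back to the centre of geometry
  atoms3 <- atom_table(name = c("C1", "C2"), resid = c(1, 1),
                       resname = rep("CHX", 2), mol_id = rep(1L, 2),
                       mol_class = rep("solvent", 2))
  co3 <- array(0, dim = c(1, 2, 3))
  co3[1, , ] <- rbind(c(1, 1, 1), c(1.4, 1, 1))
  tr3 <- trajectory(atoms3, co3, c(3, 3, 3), 1)
  expect_equal(solvent_reference_site(tr3)$sites[1, 1, ], c(1.2, 1, 1))
  ## named atom missing is an error
  atoms4 <- atom_table(name = c("HW1", "HW2"), resid = c(1, 1),
                       resname = rep("SOL", 2), mol_id = rep(1L, 2),
                       mol_class = rep("solvent", 2))
  tr4 <- trajectory(atoms4, co3, c(3, 3, 3), 1)
  expect_error(solvent_reference_site(tr4), "absent")
})

test_that("shell membership agrees with exhaustive distance enumeration", {
  fx <- make_region_fixture(n_solv = 10, n_frames = 5)
  sh <- shell_membership(fx$traj, fx$region, 0.8)
  sites <- solvent_reference_site(fx$traj)$sites
  rows <- region_atom_rows(fx$traj, fx$region)
  expect_identical(sh$member, bf_membership(fx$traj, rows, sites, 0.8))
})

test_that("membership is monotone in cutoff and translation invariant", {
  fx <- make_region_fixture(n_solv = 25, n_frames = 4)
  s1 <- shell_membership(fx$traj, fx$region, 0.5)
  s2 <- shell_membership(fx$traj, fx$region, 0.9)
  expect_true(all(s2$member[s1$member]))
  tiny <- shell_membership(fx$traj, fx$region, 1e-6)
  expect_false(any(tiny$member))
  huge <- shell_membership(fx$traj, fx$region, 10)
  expect_true(all(huge$member))
  ## rigid translation of everything (mod box) changes nothing
  shifted <- fx$traj
  shifted$coords <- (fx$traj$coords + 1.37) %% 4
  s3 <- shell_membership(shifted, fx$region, 0.5)
  expect_identical(s3$member, s1$member)
})

test_that("proximal RDF is flat for ideal-gas solvent and conserves counts", {
  ## ideal gas: iid uniform solvent positions every frame
  set.seed(17)
  box <- 4; n <- 1500; nf <- 10
  atoms <- atom_table(name = c("CA", rep("S", n)),
                      resid = c(1L, 1L + seq_len(n)),
                      resname = c("ALA", rep("SLV", n)),
                      mol_id = c(1L, 1L + seq_len(n)),
                      mol_class = c("protein", rep("solvent", n)))
  co <- array(0, dim = c(nf, n + 1, 3))
  co[, 1, ] <- 2
  co[, -1, ] <- runif(nf * n * 3, 0, box)
  tr <- trajectory(atoms, co, rep(box, 3), 1)
  reg <- region_spec("pt", "helix", c(1, 1), "Ext")
  rdf <- regional_rdf(tr, reg, r_max = 1.4, dr = 0.05,
                      n_insert = 2e4, seed = 1)
  mid <- rdf$r_centers > 0.3 & rdf$r_centers < 1.2
  expect_lt(abs(mean(rdf$g[mid]) - 1), 0.1)
  ## raw counts are conserved: every site within r_max lands in one bin
  expect_lte(sum(rdf$raw_counts), nf * n)
  expect_gt(sum(rdf$raw_counts), 0)
  ## the two normalisations agree where g plateaus
  rdf2 <- regional_rdf(tr, reg, r_max = 1.4, dr = 0.05,
                       normalization = "plateau", n_insert = 2e4, seed = 1)
  expect_lt(max(abs(rdf$g[mid] - rdf2$g[mid]), na.rm = TRUE), 0.25)
  expect_lt(abs(mean(rdf$g[mid]) / mean(rdf2$g[mid]) - 1), 0.05)
})

test_that("layered solvent produces a first-shell peak and detectable minimum", {
  ## constructed density: a shell of sites at 0.30 nm from a point
  ## region, a void to 0.50 nm, uniform placement beyond
  set.seed(23)
  n1 <- 150; n2 <- 250; box <- 4; centre <- c(2, 2, 2)
  dir <- function(n) {
    v <- matrix(rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
  }
  pos1 <- sweep(dir(n1) * 0.30, 2, centre, `+`)
  r2 <- (runif(n2, 0.5^3, 1.3^3))^(1 / 3)
  pos2 <- sweep(dir(n2) * r2, 2, centre, `+`)
  solv <- rbind(pos1, pos2)
  n <- nrow(solv)
  atoms <- atom_table(name = c("CA", rep("S", n)),
                      resid = c(1L, 1L + seq_len(n)),
                      resname = c("ALA", rep("SLV", n)),
                      mol_id = c(1L, 1L + seq_len(n)),
                      mol_class = c("protein", rep("solvent", n)))
  co <- array(0, dim = c(1, n + 1, 3))
  co[1, 1, ] <- centre
  co[1, -1, ] <- solv
  tr <- trajectory(atoms, co, rep(box, 3), 1)
  reg <- region_spec("pt", "helix", c(1, 1), "Ext")
  rdf <- regional_rdf(tr, reg, r_max = 1.3, dr = 0.04, n_insert = 5e4,
                      seed = 2)
  peak_bin <- which.max(rdf$g)
  expect_equal(rdf$r_centers[peak_bin], 0.30, tolerance = 0.1)
  cut <- first_shell_cutoff(rdf)
  expect_gt(cut$cutoff_nm, 0.30)
  expect_lt(cut$cutoff_nm, 0.52)
  expect_equal(cut$uncertainty_nm, 0.04)
})

test_that("cutoff detection on constructed curves and the defaults table", {
  r <- seq(0.025, 1.0, by = 0.05)
  g <- 1 + 1.5 * exp(-((r - 0.30) / 0.06)^2) - 0.6 * exp(-((r - 0.45) / 0.05)^2)
  rdf <- structure(list(r_centers = r, g = g, raw_counts = rep(1, length(r)),
                        normalization = "plateau", dr = 0.05),
                   class = "rdf_profile")
  cut <- first_shell_cutoff(rdf, smoothing_window = 1)
  expect_equal(cut$cutoff_nm, 0.475, tolerance = 0.06)
  flat <- structure(list(r_centers = r, g = rep(1, length(r)),
                         raw_counts = rep(1, length(r)),
                         normalization = "plateau", dr = 0.05),
                    class = "rdf_profile")
  expect_error(first_shell_cutoff(flat), "no shell structure")
  short <- structure(list(r_centers = r[1:5], g = g[1:5],
                          raw_counts = rep(1, 5), normalization = "plateau",
                          dr = 0.05), class = "rdf_profile")
  expect_error(first_shell_cutoff(short), "10 bins")
  ## the per-solvent defaults honoured when detection is skipped
  expect_equal(shell_cutoff_default("acetonitrile"), 0.5)
  expect_equal(shell_cutoff_default("n-butanol"), 0.6)
  expect_equal(shell_cutoff_default("tert-butanol"), 0.4)
  expect_equal(shell_cutoff_default("cyclohexane"), 0.7)
  expect_equal(shell_cutoff_default("acetonitrile", interior = TRUE), 0.7)
  expect_equal(shell_cutoff_default("n-butanol", interior = TRUE), 0.8)
  expect_equal(shell_cutoff_default("tert-butanol", interior = TRUE), 0.6)
  expect_equal(shell_cutoff_default("cyclohexane", interior = TRUE), 0.9)
  expect_equal(shell_cutoff_default("water"), 0.5)
  expect_equal(shell_cutoff_default("water", interior = TRUE), 0.7)
})
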