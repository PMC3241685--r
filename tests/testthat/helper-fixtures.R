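# Shared fixtures.  Everything is generated in code under fixed seeds.

ff_test <- elba_forcefield()

# Minimal hand-built system: arbitrary sites at given positions.
toy_system <- function(pos, types, box, u = NULL, vel = NULL,
                       bonds = NULL, angles = NULL, restraints = NULL,
                       species = NULL, site_name = NULL, mol = NULL,
                       ff = ff_test) {
  n <- nrow(pos)
  tidx <- match(types, ff$sites$name)
  stopifnot(!anyNA(tidx))
  if (is.null(u)) {
    u <- matrix(0, n, 3)
    u[ff$sites$dipole[tidx] > 0, 3] <- 1
  }
  sys <- elbamd:::.new_system(ff, box)
  sys$pos <- pos
  sys$vel <- if (is.null(vel)) matrix(0, n, 3) else vel
  sys$u <- u
  sys$omega <- matrix(0, n, 3)
  sys$type <- tidx
  sys$mol <- if (is.null(mol)) seq_len(n) else mol
  sys$leaflet <- rep(NA_integer_, n)
  sys$group <- if (is.null(species)) rep(0L, n) else
    ifelse(species == "water", 0L, 1L)
  sys$species <- if (is.null(species)) rep("water", n) else species
  sys$site_name <- if (is.null(site_name)) ff$sites$name[tidx] else site_name
  sys$electrons <- rep(10, n)
  if (!is.null(bonds)) sys$bonds <- bonds
  if (!is.null(angles)) sys$angles <- angles
  if (!is.null(restraints)) sys$restraints <- restraints
  class(sys) <- "elba_system"
  sys
}

# Random mixed system (waters + a few lipids) for oracle comparisons.
random_mixed_system <- function(n_lipids = 2, n_water = 150, seed = 42,
                                ff = ff_test) {
  sys <- build_random_dispersion("DOPC", n_lipids, hydration = n_water / n_lipids,
                                 total_density = 0.45, ff = ff, seed = seed)
  sys
}

# Memoised expensive runs shared between acceptance tests.
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

relax_ramp <- function(sys, ff, temperature, steps = 2000,
                       leaflet_remove = any(sys$group == 1)) {
  dts <- 0.015 * exp(seq(log(1e-3), log(1), length.out = 8))
  for (d in dts)
    sys <- run_md(sys, ff, ceiling(steps / 8),
                  sim_config("nvt", dt = d, temperature = temperature,
                             tau_t = max(20 * d, 0.05),
                             leaflet_remove = leaflet_remove,
                             e_stride = 0))$system
  sys
}

# Fake trajectory with one site per "lipid" molecule; used by the
# diffusion closed-form tests.
synthetic_com_traj <- function(xy, dt = 1, box = c(50, 50, 50)) {
  # xy: array dim c(2, n_mol, n_frames)
  nmol <- dim(xy)[2]; nf <- dim(xy)[3]
  pos <- array(0, dim = c(3, nmol, nf))
  pos[1:2, , ] <- xy
  traj <- list(pos = pos, u = array(0, dim = c(3, nmol, nf)),
               box = matrix(box, nf, 3, byrow = TRUE),
               time = (seq_len(nf) - 1) * dt,
               type = rep(match("tail", ff_test$sites$name), nmol),
               mol = seq_len(nmol),
               species = rep("DOPC", nmol),
               site_name = rep("tail_a1", nmol),
               electrons = rep(24, nmol),
               leaflet = rep(0L, nmol),
               group = rep(1L, nmol),
               ff_checksum = ff_test$checksum)
  class(traj) <- "elba_trajectory"
  traj
}
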