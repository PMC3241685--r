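# R-side surface of the MD engine: marshalling to the compiled core,
# run configuration, staged protocols, and small pure-R operations
# (drift removal, weak-coupling factors) used both by the engine tests
# and as documentation of the algorithms.

.ff_tables <- function(ff) {
  nt <- nrow(ff$sites)
  nm <- ff$sites$name
  sig <- matrix(0, nt, nt); eps <- matrix(0, nt, nt)
  rc <- matrix(0, nt, nt); rs <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    mp <- mix_params(ff, nm[i], nm[j])
    sig[i, j] <- mp$sigma_ij; eps[i, j] <- mp$epsilon_ij
    rc[i, j] <- mp$cutoff;    rs[i, j] <- mp$switch_radius
  }
  list(sigma_ij = sig, eps_ij = eps, rc_ij = rc, rs_ij = rs,
       charge = ff$sites$charge, mu = ff$sites$dipole * .DEBYE,
       mass = ff$sites$mass, inertia = ff$sites$inertia)
}

.angle_style <- function(ff) {
  st <- ff$bonded$angle_style
  if (is.null(st)) "theta" else st
}

.topo_tables <- function(sys, angle_style = "theta") {
  as_im <- function(m, cols) {
    out <- matrix(as.integer(m[, cols, drop = FALSE]), nrow = nrow(m))
    out
  }
  list(angle_style = if (identical(angle_style, "cosine")) 1L else 0L,
       angle_theta0 = as.numeric(sys$angles[, 5]) * pi / 180,
       bonds = as_im(sys$bonds, 1:2),
       bond_k = as.numeric(sys$bonds[, 3]),
       bond_r0 = as.numeric(sys$bonds[, 4]),
       angles = as_im(sys$angles, 1:3),
       angle_k = as.numeric(sys$angles[, 4]),
       angle_cos0 = cos(as.numeric(sys$angles[, 5]) * pi / 180),
       restraints = as_im(sys$restraints, 1:3),
       restraint_k = as.numeric(sys$restraints[, 4]))
}

.state_list <- function(sys) {
  list(pos = sys$pos, vel = sys$vel, u = sys$u, omega = sys$omega,
       type = as.integer(sys$type),
       leaflet = as.integer(sys$leaflet),
       group = as.integer(sys$group),
       box = sys$box, time = sys$time)
}

.dof <- function(sys, ff, com_remove = TRUE, leaflet_remove = FALSE) {
  n0 <- sum(sys$group == 0); n1 <- sum(sys$group == 1)
  has_dip <- ff$sites$dipole[sys$type] > 0
  r0 <- 2 * sum(has_dip & sys$group == 0)
  r1 <- 2 * sum(has_dip & sys$group == 1)
  t0 <- 3 * n0; t1 <- 3 * n1
  if (com_remove) {
    if (n1 == 0) t0 <- t0 - 3 else t1 <- t1 - 3
  }
  if (leaflet_remove && n1 > 0) t1 <- t1 - 4
  list(trans = c(t0, t1), rot = c(r0, r1),
       total = t0 + t1 + r0 + r1)
}

#' Simulation configuration
#'
#' Collects the run-control parameters of the engine.  Defaults follow the
#' force field's reference protocol: 15 fs timestep, weak-coupling
#' temperature control with separate lipid and water baths (translational
#' and rotational degrees of freedom coupled independently), weak-coupling
#' pressure control at 1 atm, removal of the net system momentum every
#' step and, for bilayers, of the net lateral velocity of each monolayer.
#'
#' @param ensemble One of `"nve"`, `"nvt"`, `"npt-iso"`, `"npt-semi"`,
#'   `"npt-aniso"`.
#' @param dt Timestep, ps (default 0.015 = 15 fs).
#' @param temperature Target temperature, K (recycled to the water and
#'   lipid baths; give a length-2 vector `c(water, lipid)` to split).
#' @param pressure Target pressure, atm.
#' @param tau_t,tau_p Coupling time constants, ps.
#' @param kappa Isothermal compressibility, atm^-1.
#' @param skin Neighbour-list skin, nm.
#' @param com_remove Remove the net mass-centre velocity every step.
#' @param leaflet_remove Remove each monolayer's net lateral velocity
#'   every step (bilayer systems).
#' @param e_stride Steps between energy-log rows (0 = off).
#' @param x_stride Steps between stored trajectory frames (0 = off).
#' @param prof_stride Steps between slab pressure-profile accumulations
#'   (0 = off).
#' @param slab_dz Target slab thickness for profiles, nm.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ensemble = "nvt", dt = 0.015, temperature = 303,
                       pressure = 1, tau_t = 1, tau_p = 5,
                       kappa = 4.6e-5, skin = 0.2,
                       com_remove = ensemble != "nve",
                       leaflet_remove = FALSE,
                       e_stride = 20, x_stride = 0, prof_stride = 0,
                       slab_dz = 0.1) {
  ensemble <- match.arg(ensemble,
                        c("nve", "nvt", "npt-iso", "npt-semi", "npt-aniso"))
  temperature <- rep(temperature, length.out = 2)
  cfg <- list(ensemble = ensemble, dt = dt, temperature = temperature,
              pressure = pressure, tau_t = tau_t, tau_p = tau_p,
              kappa = kappa, skin = skin, com_remove = com_remove,
              leaflet_remove = leaflet_remove, e_stride = e_stride,
              x_stride = x_stride, prof_stride = prof_stride,
              slab_dz = slab_dz)
  class(cfg) <- "sim_config"
  cfg
}

.elog_names <- c("step", "time", "E_lj", "E_coul", "E_qd", "E_dd",
                 "E_bond", "E_angle", "E_restraint", "KE_trans", "KE_rot",
                 "T", "Pxx", "Pyy", "Pzz", "Lx", "Ly", "Lz", "E_total")

#' Propagate a system by molecular dynamics
#'
#' Runs `nsteps` of coupled translational/rotational velocity-Verlet
#' dynamics with the requested ensemble couplings.  Nonbonded interactions
#' use per-pair shifted-force cutoffs (0.9 nm water-water, 1.2 nm
#' otherwise); directly bonded (1-2) pairs are excluded.  The run is
#' fully deterministic: no randomness enters after system construction.
#'
#' @param sys An `elba_system`.
#' @param ff The [elba_forcefield()] the system was built with.
#' @param nsteps Number of steps.
#' @param cfg A [sim_config()].
#' @return An `elba_run`: list with `system` (final state), `elog`
#'   (data frame of energies, temperature, pressure tensor, box), `traj`
#'   (an `elba_trajectory` or `NULL`), `profile` (slab pressure-profile
#'   accumulators or `NULL`), `status` (`"ok"` or `"unstable"`; an
#'   unstable run returns the last logged state), and `config`.
#' @export
run_md <- function(sys, ff, nsteps, cfg = sim_config()) {
  stopifnot(inherits(sys, "elba_system"), inherits(ff, "elba_forcefield"))
  if (!identical(sys$ff_checksum, ff$checksum))
    warning("system was built with a different parameter file")
  dof <- .dof(sys, ff, cfg$com_remove, cfg$leaflet_remove)
  baro_mode <- switch(cfg$ensemble, "nve" = 0L, "nvt" = 0L,
                      "npt-iso" = 1L, "npt-semi" = 2L, "npt-aniso" = 3L)
  nslab <- max(10L, as.integer(round(sys$box[3] / cfg$slab_dz)))
  ctrl <- list(nsteps = as.integer(nsteps), dt = cfg$dt, skin = cfg$skin,
               thermo_on = cfg$ensemble != "nve",
               T0_water = cfg$temperature[1], T0_lipid = cfg$temperature[2],
               tau_t = cfg$tau_t,
               dof_trans = dof$trans, dof_rot = dof$rot,
               dof_total = dof$total,
               baro_mode = baro_mode, tau_p = cfg$tau_p, kappa = cfg$kappa,
               P0 = cfg$pressure,
               com_remove = cfg$com_remove,
               leaflet_remove = cfg$leaflet_remove,
               e_stride = as.integer(cfg$e_stride),
               x_stride = as.integer(cfg$x_stride),
               prof_stride = as.integer(cfg$prof_stride),
               prof_nslab = nslab)
  out <- md_run_cpp(.state_list(sys), .ff_tables(ff),
                    .topo_tables(sys, .angle_style(ff)), ctrl)

  new_sys <- sys
  st <- out$state
  new_sys$pos <- st$pos; new_sys$vel <- st$vel
  new_sys$u <- st$u; new_sys$omega <- st$omega
  new_sys$box <- st$box; new_sys$time <- st$time

  elog <- as.data.frame(out$elog)
  names(elog) <- .elog_names

  traj <- NULL
  nf <- length(out$traj_time)
  if (nf > 0) {
    n <- nrow(sys$pos)
    traj <- list(pos = array(out$traj_pos, dim = c(3, n, nf)),
                 u = array(out$traj_u, dim = c(3, n, nf)),
                 box = matrix(out$traj_box, ncol = 3, byrow = TRUE),
                 time = out$traj_time,
                 type = sys$type, mol = sys$mol, species = sys$species,
                 site_name = sys$site_name, electrons = sys$electrons,
                 leaflet = sys$leaflet, group = sys$group,
                 ff_checksum = sys$ff_checksum)
    class(traj) <- "elba_trajectory"
  }

  profile <- NULL
  if (out$prof_nacc > 0) {
    nsl <- out$prof_nslab
    Lz <- new_sys$box[3]
    z <- (seq_len(nsl) - 0.5) * Lz / nsl - Lz / 2
    profile <- data.frame(z = z,
                          P_T = out$prof_PT / out$prof_nacc,
                          P_N = out$prof_PN / out$prof_nacc)
    attr(profile, "n_frames") <- out$prof_nacc
  }

  res <- list(system = new_sys, elog = elog, traj = traj, profile = profile,
              status = out$status, config = cfg)
  class(res) <- "elba_run"
  res
}

#' @export
print.elba_run <- function(x, ...) {
  cat("elba_run:", x$status, "-", nrow(x$elog), "log rows, t =",
      x$system$time, "ps\n")
  if (nrow(x$elog)) {
    tail1 <- x$elog[nrow(x$elog), ]
    cat(sprintf("  T = %.1f K, E = %.2f kJ/mol, box %s nm\n", tail1$T,
                tail1$E_total,
                paste(signif(unlist(tail1[c("Lx", "Ly", "Lz")]), 5),
                      collapse = " x ")))
  }
  invisible(x)
}

#' Staged equilibration and production protocol
#'
#' Reference protocol for freshly built systems: (1) relaxation at
#' constant volume with the timestep ramped geometrically from a tiny
#' value up to the production timestep, (2) constant-volume equilibration,
#' (3) constant-pressure equilibration, then (4) production with the
#' requested observers.  Every stage uses the same thermostat targets.
#'
#' @param sys An `elba_system`.
#' @param ff The force field.
#' @param temperature Target temperature, K.
#' @param ensemble Production ensemble (see [sim_config()]).
#' @param relax_steps,nvt_ps,npt_ps,production_ps Stage lengths (steps for
#'   the ramp; picoseconds otherwise).
#' @param dt Production timestep, ps.
#' @param leaflet_remove Passed to [sim_config()].
#' @param e_stride,x_stride,prof_stride Observer strides for production.
#' @return The production `elba_run` (its `$system` carries the final
#'   state; equilibration output is discarded).
#' @export
run_protocol <- function(sys, ff, temperature = 303,
                         ensemble = "npt-semi",
                         relax_steps = 2000, nvt_ps = 10, npt_ps = 30,
                         production_ps = 150, dt = 0.015,
                         leaflet_remove = any(sys$group == 1),
                         e_stride = 20, x_stride = 100, prof_stride = 0) {
  # stage 1: ramped-timestep relaxation, NVT
  dts <- dt * exp(seq(log(1e-3), log(1), length.out = 10))
  for (d in dts) {
    cfg <- sim_config("nvt", dt = d, temperature = temperature,
                      tau_t = max(20 * d, 0.05),
                      leaflet_remove = leaflet_remove, e_stride = 0)
    sys <- run_md(sys, ff, ceiling(relax_steps / 10), cfg)$system
  }
  # stage 2: NVT
  cfg <- sim_config("nvt", dt = dt, temperature = temperature,
                    leaflet_remove = leaflet_remove, e_stride = 0)
  sys <- run_md(sys, ff, ceiling(nvt_ps / dt), cfg)$system
  # stage 3: NPT equilibration
  cfg <- sim_config(ensemble, dt = dt, temperature = temperature,
                    leaflet_remove = leaflet_remove, e_stride = 0)
  sys <- run_md(sys, ff, ceiling(npt_ps / dt), cfg)$system
  # stage 4: production
  cfg <- sim_config(ensemble, dt = dt, temperature = temperature,
                    leaflet_remove = leaflet_remove, e_stride = e_stride,
                    x_stride = x_stride, prof_stride = prof_stride)
  run_md(sys, ff, ceiling(production_ps / dt), cfg)
}

#' Forces, torques and energy report for a configuration
#'
#' Single-point evaluation of the full ELBA energy surface: all nonbonded
#' terms with their per-pair cutoffs, bonds, angles and dipole restraints.
#'
#' @inheritParams run_md
#' @param skin Neighbour-list skin, nm.
#' @return List with `forces` (N x 3, kJ/mol/nm), `torques` (N x 3,
#'   kJ/mol), `energies` (named vector per term), `potential` (their sum),
#'   `kinetic_trans`, `kinetic_rot`, `virial` (diagonal), `pressure`
#'   (diagonal, atm) and `npairs`.
#' @export
compute_forces <- function(sys, ff, skin = 0.2) {
  out <- eval_forces_cpp(.state_list(sys), .ff_tables(ff),
                         .topo_tables(sys, .angle_style(ff)), skin)
  mass <- ff$sites$mass[sys$type]
  inertia <- ff$sites$inertia[sys$type]
  ke_t <- 0.5 * sum(mass * rowSums(sys$vel^2))
  ke_r <- 0.5 * sum(inertia * rowSums(sys$omega^2))
  V <- prod(sys$box)
  kin_diag <- colSums(sys$vel^2 * mass)
  out$potential <- sum(out$energies)
  out$kinetic_trans <- ke_t
  out$kinetic_rot <- ke_r
  out$pressure <- (kin_diag + out$virial) / V * .ATM
  out
}

#' Neighbour list under the minimum-image convention
#'
#' Returns every site pair within `cutoff_ij + skin`, excluding directly
#' bonded (1-2) pairs, exactly as used by the force loop.
#'
#' @inheritParams compute_forces
#' @return Two-column integer matrix of 1-based site indices (i < j).
#' @export
neighbor_list <- function(sys, ff, skin = 0.2) {
  neighbor_pairs_cpp(.state_list(sys), .ff_tables(ff),
                     .topo_tables(sys, .angle_style(ff)), skin)
}

#' Remove net drift from a system
#'
#' Zeroes the total mass-centre momentum and, for bilayer systems, the
#' net lateral (x, y) momentum of each monolayer, leaving normal
#' components untouched.
#'
#' @inheritParams compute_forces
#' @return The system with corrected velocities.
#' @export
remove_drift <- function(sys, ff) {
  m <- ff$sites$mass[sys$type]
  vc <- colSums(sys$vel * m) / sum(m)
  sys$vel <- sweep(sys$vel, 2, vc)
  if (any(sys$group == 1)) {
    # per-group lateral removal (each monolayer, plus water so the
    # total momentum stays zero)
    sels <- list(sys$group == 1 & !is.na(sys$leaflet) & sys$leaflet == 0,
                 sys$group == 1 & !is.na(sys$leaflet) & sys$leaflet == 1,
                 sys$group == 0)
    for (sel in sels) {
      if (!any(sel)) next
      vlat <- colSums(sys$vel[sel, 1:2, drop = FALSE] * m[sel]) / sum(m[sel])
      sys$vel[sel, 1] <- sys$vel[sel, 1] - vlat[1]
      sys$vel[sel, 2] <- sys$vel[sel, 2] - vlat[2]
    }
  }
  sys
}

#' Berendsen weak-coupling scale factors
#'
#' `berendsen_lambda` is the velocity scale factor
#' `sqrt(1 + (dt/tau)(T0/T - 1))` applied per thermostat group;
#' `berendsen_mu` the box scale factor `(1 - (kappa dt/tau)(P0 - P))^(1/3)`.
#'
#' @param T_inst,T0 Instantaneous and target temperature, K.
#' @param P_inst,P0 Instantaneous and target pressure, atm.
#' @param dt Timestep, ps.
#' @param tau Coupling time constant, ps.
#' @param kappa Compressibility, atm^-1.
#' @return Dimensionless scale factor.
#' @export
berendsen_lambda <- function(T_inst, T0, dt, tau) {
  sqrt(pmax(1 + (dt / tau) * (T0 / T_inst - 1), 0))
}

#' @rdname berendsen_lambda
#' @export
berendsen_mu <- function(P_inst, P0, dt, tau, kappa = 4.6e-5) {
  (1 - kappa * dt / tau * (P0 - P_inst))^(1 / 3)
}

#' Weak-coupling thermostat step (reference implementation)
#'
#' Scales the translational (and, for dipole carriers, rotational)
#' velocities of each coupling group (water/lipid, translational and
#' rotational independently) by the Berendsen factor computed from that
#' group's own kinetic temperature.  This is the same operation the
#' compiled engine applies once per step.
#'
#' @inheritParams compute_forces
#' @param T0 Target temperature, K (length 1 or 2: water, lipid).
#' @param dt Timestep, ps.
#' @param tau Time constant, ps.
#' @return The system with scaled velocities.
#' @export
weak_coupling_thermostat <- function(sys, ff, T0, dt = 0.015, tau = 1) {
  T0 <- rep(T0, length.out = 2)
  m <- ff$sites$mass[sys$type]
  inertia <- ff$sites$inertia[sys$type]
  has_dip <- ff$sites$dipole[sys$type] > 0
  dof <- .dof(sys, ff, com_remove = FALSE)
  for (g in 0:1) {
    sel <- sys$group == g
    if (!any(sel)) next
    ke <- 0.5 * sum(m[sel] * rowSums(sys$vel[sel, , drop = FALSE]^2))
    Tt <- 2 * ke / (dof$trans[g + 1] * .kB)
    sys$vel[sel, ] <- sys$vel[sel, ] * berendsen_lambda(Tt, T0[g + 1], dt, tau)
    selr <- sel & has_dip
    if (any(selr)) {
      ker <- 0.5 * sum(inertia[selr] *
                         rowSums(sys$omega[selr, , drop = FALSE]^2))
      Tr <- 2 * ker / (dof$rot[g + 1] * .kB)
      sys$omega[selr, ] <- sys$omega[selr, ] *
        berendsen_lambda(Tr, T0[g + 1], dt, tau)
    }
  }
  sys
}

#' Weak-coupling barostat step (reference implementation)
#'
#' Scales the box and all coordinates toward the target pressure.
#' Isotropic mode uses one factor from the mean pressure; semi-isotropic
#' scales z from `Pzz` and x-y jointly from `(Pxx+Pyy)/2` (the interface
#' stays square); anisotropic scales each axis independently.
#'
#' @inheritParams compute_forces
#' @param mode `"isotropic"`, `"semi-isotropic"` or `"anisotropic"`.
#' @param P0 Target pressure, atm.
#' @param dt Timestep, ps.
#' @param tau,kappa Coupling constant (ps) and compressibility (atm^-1).
#' @return The system with scaled box and coordinates.
#' @export
weak_coupling_barostat <- function(sys, ff, mode = "semi-isotropic",
                                   P0 = 1, dt = 0.015, tau = 5,
                                   kappa = 4.6e-5) {
  mode <- match.arg(mode, c("isotropic", "semi-isotropic", "anisotropic"))
  P <- compute_forces(sys, ff)$pressure
  mu3 <- function(p) (1 - kappa * dt / tau * (P0 - p))^(1 / 3)
  s <- switch(mode,
    isotropic = rep(mu3(mean(P)), 3),
    `semi-isotropic` = c(rep(mu3(mean(P[1:2])), 2), mu3(P[3])),
    anisotropic = c(mu3(P[1]), mu3(P[2]), mu3(P[3])))
  sys$box <- sys$box * s
  sys$pos <- sweep(sys$pos, 2, s, "*")
  sys
}

#' Kinetic temperature of a system
#'
#' @inheritParams compute_forces
#' @param what `"total"`, `"trans"` or `"rot"`.
#' @return Temperature in K.
#' @export
kinetic_temperature <- function(sys, ff, what = "total") {
  what <- match.arg(what, c("total", "trans", "rot"))
  m <- ff$sites$mass[sys$type]
  inertia <- ff$sites$inertia[sys$type]
  dof <- .dof(sys, ff, com_remove = TRUE)
  ke_t <- 0.5 * sum(m * rowSums(sys$vel^2))
  ke_r <- 0.5 * sum(inertia * rowSums(sys$omega^2))
  switch(what,
         total = 2 * (ke_t + ke_r) / (dof$total * .kB),
         trans = 2 * ke_t / (sum(dof$trans) * .kB),
         rot = 2 * ke_r / (max(sum(dof$rot), 1) * .kB))
}

#' Mass density of a system
#'
#' Uses the physical (represented atom-group) masses, not the inertial
#' site masses: the water site's inertial mass is a dynamical tuning
#' parameter, while the density of the represented liquid is defined by
#' the true water molar mass.
#'
#' @inheritParams compute_forces
#' @return Density in g/cm^3.
#' @export
mass_density <- function(sys, ff) {
  sum(ff$sites$mass_phys[sys$type]) * .AMU_NM3 / prod(sys$box)
}
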