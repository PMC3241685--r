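# Membrane observables computed from trajectories and run output.
#
# Depth-resolved profiles subdivide the box into slabs perpendicular to
# the bilayer normal (z), with the slab count fixed so the thickness is
# about 0.1 nm and the actual thickness recomputed per frame as the box
# fluctuates.  z = 0 sits at the instantaneous lipid mass centre (box
# centre for pure water systems).  Profiles are not symmetrised over the
# two monolayers.

#' Wrap a single configuration as a one-frame trajectory
#'
#' @param sys An `elba_system`.
#' @return An `elba_trajectory` with one frame.
#' @export
as_trajectory <- function(sys) {
  n <- nrow(sys$pos)
  traj <- list(pos = array(t(sys$pos), dim = c(3, n, 1)),
               u = array(t(sys$u), dim = c(3, n, 1)),
               box = matrix(sys$box, 1, 3),
               time = sys$time,
               type = sys$type, mol = sys$mol, species = sys$species,
               site_name = sys$site_name, electrons = sys$electrons,
               leaflet = sys$leaflet, group = sys$group,
               ff_checksum = sys$ff_checksum)
  class(traj) <- "elba_trajectory"
  traj
}

#' @export
print.elba_trajectory <- function(x, ...) {
  cat("elba_trajectory:", dim(x$pos)[2], "sites,", dim(x$pos)[3],
      "frames, t =", signif(range(x$time), 6), "ps\n")
  invisible(x)
}

.n_frames <- function(traj) dim(traj$pos)[3]

# Per-frame slab z coordinate: shifted so z=0 is at the lipid mass centre
# (or mid-box), wrapped into [0, Lz).
.slab_z <- function(traj, f, mass) {
  z <- traj$pos[3, , f]
  Lz <- traj$box[f, 3]
  if (any(traj$group == 1)) {
    sel <- traj$group == 1
    zc <- sum(z[sel] * mass[sel]) / sum(mass[sel])
  } else zc <- Lz / 2
  zs <- z - zc + Lz / 2
  zs - Lz * floor(zs / Lz)
}

.slab_grid <- function(traj, target_dz) {
  max(10L, as.integer(round(traj$box[1, 3] / target_dz)))
}

#' Electron density profile
#'
#' Assigns all electrons of the underlying atom group to the mass centre
#' of each CG site and bins them into slabs along z, frame-averaged.
#' The integral of the profile over the box times the interface area
#' equals the total electron count.
#'
#' @param traj An `elba_trajectory`.
#' @param ff The force field (for site masses used in centring).
#' @param target_dz Target slab thickness, nm.
#' @return Data frame with `z` (nm, slab centres, 0 = bilayer centre) and
#'   `density` (e/nm^3); attribute `total_electrons`.
#' @export
electron_density_profile <- function(traj, ff = elba_forcefield(),
                                     target_dz = 0.1) {
  nslab <- .slab_grid(traj, target_dz)
  mass <- ff$sites$mass[traj$type]
  nf <- .n_frames(traj)
  acc <- numeric(nslab)
  for (f in seq_len(nf)) {
    Lz <- traj$box[f, 3]
    dz <- Lz / nslab
    zs <- .slab_z(traj, f, mass)
    s <- pmin(pmax(floor(zs / dz), 0), nslab - 1) + 1
    counts <- as.numeric(tapply(traj$electrons, factor(s, levels = 1:nslab),
                                sum, default = 0))
    vslab <- traj$box[f, 1] * traj$box[f, 2] * dz
    acc <- acc + counts / vslab
  }
  Lz <- traj$box[nf, 3]
  out <- data.frame(z = (seq_len(nslab) - 0.5) * Lz / nslab - Lz / 2,
                    density = acc / nf)
  attr(out, "total_electrons") <- sum(traj$electrons)
  attr(out, "nslab") <- nslab
  out
}

#' Lateral pressure profile
#'
#' The difference between the tangential pressure (mean of the xx and yy
#' pressure-tensor components) and the normal (zz) pressure per slab,
#' from the per-slab kinetic + virial accumulators recorded during the
#' run (Harasima assignment: each pair's virial split half to the slab
#' of each partner).  Its integral over z is the surface tension.
#'
#' @param run An `elba_run` produced with `prof_stride > 0`.
#' @return Data frame with `z` (nm), `P_T`, `P_N` and `pi = P_T - P_N`
#'   (atm).
#' @export
lateral_pressure_profile <- function(run) {
  if (is.null(run$profile))
    stop("run has no slab accumulators; rerun with prof_stride > 0")
  out <- run$profile
  out$pi <- out$P_T - out$P_N
  out
}

#' Curvature elastic constants from the lateral pressure profile
#'
#' First and second integral moments of the lateral pressure profile,
#' integrated per monolayer outward from the bilayer centre and averaged
#' over the two monolayers; the monolayer spontaneous curvature
#' `c0 = -M1 / kappa_m` with `kappa_m` half the bilayer bending modulus;
#' the pivotal-surface distance `delta` as the half-distance between the
#' two global minima of the profile; and the Gaussian curvature modulus
#' from the zero-tension pivotal-plane expansion
#' `kappa_G = M2 - 2 delta M1`.  Negative `c0` means bending toward the
#' water phase.
#'
#' @param profile Data frame with `z` (nm) and `pi` (atm), e.g. from
#'   [lateral_pressure_profile()] or [synthetic_profile()].
#' @param kc_bilayer Bilayer bending modulus, kJ/mol (e.g. from
#'   [structural_summary()]); `NA` leaves `c0` unset.
#' @param temperature Temperature (K) for kBT-unit conversions.
#' @return List of class `curvature_elastics`: `M1` (kJ/mol/nm^2),
#'   `M2` (kJ/mol/nm), `kappa_m` (kJ/mol), `c0` (nm^-1), `delta` (nm),
#'   `kappa_G` (kJ/mol), plus `M1_kBT_nm`, `kappa_G_kBT` conveniences.
#' @export
curvature_elastics <- function(profile, kc_bilayer = NA,
                               temperature = 303) {
  z <- profile$z
  p <- profile$pi / .ATM                      # kJ/(mol nm^3)
  dz <- if (length(z) > 1) stats::median(diff(z)) else 1
  up <- z > 0; lo <- z < 0
  M1 <- mean(c(sum(z[up] * p[up]) * dz, sum(-z[lo] * p[lo]) * dz))
  M2 <- mean(c(sum(z[up]^2 * p[up]) * dz, sum(z[lo]^2 * p[lo]) * dz))
  zmin_up <- z[up][which.min(p[up])]
  zmin_lo <- z[lo][which.min(p[lo])]
  delta <- (zmin_up - zmin_lo) / 2
  kappa_m <- kc_bilayer / 2
  c0 <- if (is.na(kappa_m)) NA_real_ else -M1 / kappa_m
  kG <- M2 - 2 * delta * M1
  kT <- .kB * temperature
  out <- list(M1 = M1, M2 = M2, kappa_m = kappa_m, c0 = c0,
              delta = delta, kappa_G = kG,
              M1_kBT_nm = M1 / kT, kappa_G_kBT = kG / kT)
  class(out) <- "curvature_elastics"
  out
}

#' @export
print.curvature_elastics <- function(x, ...) {
  cat(sprintf(
    "curvature elastics: M1 = %.4g kJ/mol/nm^2, M2 = %.4g kJ/mol/nm\n",
    x$M1, x$M2))
  cat(sprintf("  c0 = %.4g 1/nm, delta = %.3g nm, kappa_G = %.4g kJ/mol\n",
              x$c0, x$delta, x$kappa_G))
  invisible(x)
}

#' Electrostatic potential profile and dipole potential
#'
#' Integrates the slab-binned headgroup charge density twice and the
#' z-projected point-dipole density (water + glycerol + ester dipoles)
#' once, divided by the vacuum permittivity, to give the transmembrane
#' electrostatic potential referenced to zero in bulk water.  The dipole
#' potential is `delta_psi = psi(bilayer centre) - psi(bulk water)`.  A
#' per-species decomposition (each species' own charges/dipoles run
#' through the same integration) is attached.
#'
#' @inheritParams electron_density_profile
#' @return Data frame with `z`, `rho_q` (e/nm^3), `P_z` (e/nm^2 per nm),
#'   `psi` (V) and one `psi_<species>` column per contributing site type;
#'   attributes `delta_psi` (V) and `contributions` (named vector of
#'   per-species core-minus-water potentials).
#' @export
electrostatic_potential_profile <- function(traj, ff = elba_forcefield(),
                                            target_dz = 0.1) {
  nslab <- .slab_grid(traj, target_dz)
  mass <- ff$sites$mass[traj$type]
  q <- ff$sites$charge[traj$type]
  mu <- ff$sites$dipole[traj$type] * .DEBYE     # e nm
  tname <- ff$sites$name[traj$type]
  nf <- .n_frames(traj)
  species <- ff$sites$name[ff$sites$charge != 0 | ff$sites$dipole > 0]
  species <- intersect(species, unique(tname))

  rho_acc <- matrix(0, nslab, length(species) + 1)
  pz_acc <- matrix(0, nslab, length(species) + 1)
  for (f in seq_len(nf)) {
    Lz <- traj$box[f, 3]
    dz <- Lz / nslab
    vslab <- traj$box[f, 1] * traj$box[f, 2] * dz
    zs <- .slab_z(traj, f, mass)
    s <- pmin(pmax(floor(zs / dz), 0), nslab - 1) + 1
    sf <- factor(s, levels = 1:nslab)
    muz <- mu * traj$u[3, , f]
    rho_acc[, 1] <- rho_acc[, 1] +
      as.numeric(tapply(q, sf, sum, default = 0)) / vslab
    pz_acc[, 1] <- pz_acc[, 1] +
      as.numeric(tapply(muz, sf, sum, default = 0)) / vslab
    for (k in seq_along(species)) {
      sel <- tname == species[k]
      rho_acc[, k + 1] <- rho_acc[, k + 1] +
        as.numeric(tapply(q * sel, sf, sum, default = 0)) / vslab
      pz_acc[, k + 1] <- pz_acc[, k + 1] +
        as.numeric(tapply(muz * sel, sf, sum, default = 0)) / vslab
    }
  }
  rho_acc <- rho_acc / nf
  pz_acc <- pz_acc / nf
  Lz <- traj$box[nf, 3]
  dz <- Lz / nslab
  z <- (seq_len(nslab) - 0.5) * dz - Lz / 2

  integrate_psi <- function(rho, pz) {
    efield <- cumsum(rho) * dz               # e/nm^2 / eps0 later
    psi <- (-cumsum(efield) * dz + cumsum(pz) * dz) * .INV_EPS0
    psi - psi[1]
  }
  psi <- integrate_psi(rho_acc[, 1], pz_acc[, 1])
  # reference: mean over the outermost 10% of slabs on both sides (bulk water)
  edge <- unique(c(seq_len(max(1, nslab %/% 10)),
                   nslab - seq_len(max(1, nslab %/% 10)) + 1))
  core <- which(abs(z) <= dz * 2)
  psi <- psi - mean(psi[edge])
  out <- data.frame(z = z, rho_q = rho_acc[, 1], P_z = pz_acc[, 1],
                    psi = psi)
  contrib <- numeric(length(species))
  for (k in seq_along(species)) {
    pk <- integrate_psi(rho_acc[, k + 1], pz_acc[, k + 1])
    pk <- pk - mean(pk[edge])
    out[[paste0("psi_", species[k])]] <- pk
    contrib[k] <- mean(pk[core])
  }
  names(contrib) <- species
  attr(out, "delta_psi") <- mean(psi[core])
  attr(out, "contributions") <- contrib
  out
}

# Tail-bond list (i, j, position 1..4, chain) derived from site names.
.tail_bonds <- function(traj) {
  out <- list()
  for (m in unique(traj$mol[traj$group == 1])) {
    idx <- which(traj$mol == m)
    nm <- traj$site_name[idx]
    for (ch in c("a", "b")) {
      sites <- idx[match(paste0("tail_", ch, 1:5), nm)]
      if (any(is.na(sites))) next
      out[[length(out) + 1]] <- cbind(sites[1:4], sites[2:5], 1:4)
    }
  }
  do.call(rbind, out)
}

#' Tail segmental order parameter
#'
#' Second-Legendre order parameter `S = <(3 cos^2 th - 1)/2>` of each
#' tail-tail bond relative to the bilayer normal (z), averaged over
#' frames; the global value averages the four bonds of each tail, then
#' all tails.  `S = 1` for bonds along the normal, `-0.5` in-plane, `0`
#' for isotropic orientations.
#'
#' @param traj An `elba_trajectory` containing lipids.
#' @return List with `global`, `per_position` (mean per bond position
#'   1-4 from the ester end) and `n_bonds`.
#' @export
order_parameter <- function(traj) {
  tb <- .tail_bonds(traj)
  if (is.null(tb) || nrow(tb) == 0) stop("no lipid tails in trajectory")
  nf <- .n_frames(traj)
  s_acc <- numeric(nrow(tb))
  for (f in seq_len(nf)) {
    box <- traj$box[f, ]
    d <- traj$pos[, tb[, 2], f] - traj$pos[, tb[, 1], f]
    d <- d - box * round(d / box)
    c2 <- (d[3, ]^2) / colSums(d^2)
    s_acc <- s_acc + (3 * c2 - 1) / 2
  }
  s_bond <- s_acc / nf
  list(global = mean(s_bond),
       per_position = tapply(s_bond, tb[, 3], mean),
       n_bonds = nrow(tb))
}

#' Structural summary of a bilayer run
#'
#' Area per lipid from the box trace, volume per lipid after subtracting
#' the bulk-water volume, headgroup-peak bilayer thickness from the
#' electron density profile, headgroup P-N dipole magnitude and tilt,
#' area compressibility modulus from the area fluctuations
#' (`K_A = kB T <A> / var(A)`), and the bending modulus through the
#' polymer-brush relation `k_c = K_A (D_HH - h0)^2 / 24`.
#'
#' @param run An `elba_run` of a bilayer with an energy log and stored
#'   trajectory frames.
#' @param ff The force field.
#' @param v_w Bulk volume per water site, nm^3 (measure it from a bulk
#'   water run at the same state point).
#' @param h0 Polymer-brush deformable-thickness offset, nm.
#' @return List of class `structural_summary`: `area_per_lipid` (A^2),
#'   `volume_per_lipid` (nm^3), `thickness` (nm), `head_dipole` (D),
#'   `head_tilt` (deg, from the bilayer plane), `K_A` (dyn/cm), `k_c_kBT`,
#'   `n_lipids`.
#' @export
structural_summary <- function(run, ff = elba_forcefield(), v_w = 0.0667,
                               h0 = 1.0) {
  sys <- run$system
  nlip <- length(unique(sys$mol[sys$group == 1]))
  if (nlip == 0) stop("not a bilayer run")
  if (nlip > 256)
    warning("profiles assume a flat bilayer; undulations in systems of ",
            "this size blur slab averages and shrink the projected area")
  elog <- run$elog
  if (!nrow(elog)) stop("run has no energy log")
  A <- elog$Lx * elog$Ly
  V <- A * elog$Lz
  temperature <- mean(elog$T)
  n_w <- sum(run$system$group == 0)
  area_per_lipid <- 2 * mean(A) / nlip * 100          # A^2
  vol_per_lipid <- (mean(V) - n_w * v_w) / nlip
  varA <- stats::var(A)
  if (!is.finite(varA) || varA <= 0) {
    warning("zero area variance: K_A is not finite")
    K_A <- Inf
  } else {
    K_A <- .kB * temperature * mean(A) / varA          # kJ/(mol nm^2)
  }

  thickness <- NA_real_
  if (!is.null(run$traj)) {
    ed <- electron_density_profile(run$traj, ff)
    up <- ed$z > 0; lo <- ed$z < 0
    thickness <- ed$z[up][which.max(ed$density[up])] -
      ed$z[lo][which.max(ed$density[lo])]
  }
  k_c <- if (is.finite(K_A) && !is.na(thickness))
    K_A * (thickness - h0)^2 / 24 else NA_real_       # kJ/mol

  # headgroup P->N dipole from the final configuration ensemble
  hd <- hb <- NULL
  if (!is.null(run$traj)) {
    traj <- run$traj
    qmag <- abs(ff$sites$charge[match("phosphate", ff$sites$name)])
    dm <- c(); tl <- c()
    heads <- which(traj$site_name == "head")
    phos <- which(traj$site_name == "phosphate")
    for (f in seq_len(.n_frames(traj))) {
      d <- traj$pos[, heads, f] - traj$pos[, phos, f]
      d <- d - traj$box[f, ] * round(d / traj$box[f, ])
      len <- sqrt(colSums(d^2))
      dm <- c(dm, qmag * len / .DEBYE)
      tl <- c(tl, asin(pmin(abs(d[3, ]) / len, 1)) * 180 / pi)
    }
    hd <- mean(dm); hb <- mean(tl)
  }

  out <- list(area_per_lipid = area_per_lipid,
              volume_per_lipid = vol_per_lipid,
              thickness = thickness,
              head_dipole = if (is.null(hd)) NA_real_ else hd,
              head_tilt = if (is.null(hb)) NA_real_ else hb,
              K_A = K_A * .DYNCM,
              k_c_kBT = k_c / (.kB * temperature),
              n_lipids = nlip, temperature = temperature)
  class(out) <- "structural_summary"
  out
}

#' @export
print.structural_summary <- function(x, ...) {
  cat(sprintf("bilayer structural summary (%d lipids, %.0f K):\n",
              x$n_lipids, x$temperature))
  cat(sprintf("  A_L = %.1f A^2   V_L = %.3f nm^3   D_HH = %.2f nm\n",
              x$area_per_lipid, x$volume_per_lipid, x$thickness))
  cat(sprintf("  head dipole = %.1f D (tilt %.0f deg from plane)\n",
              x$head_dipole, x$head_tilt))
  cat(sprintf("  K_A = %.0f dyn/cm   k_c = %.1f kBT\n", x$K_A, x$k_c_kBT))
  invisible(x)
}

# Centre-of-mass trajectories per molecule for a species selection.
.com_traj <- function(traj, ff, species) {
  mass <- ff$sites$mass[traj$type]
  sel <- traj$species == species
  mols <- unique(traj$mol[sel])
  nf <- .n_frames(traj)
  out <- array(0, dim = c(3, length(mols), nf))
  for (k in seq_along(mols)) {
    idx <- which(traj$mol == mols[k])
    w <- mass[idx] / sum(mass[idx])
    acc <- matrix(0, 3, nf)
    for (q in seq_along(idx))
      acc <- acc + w[q] * traj$pos[, idx[q], ]
    out[, k, ] <- acc
  }
  out
}

#' Mean-square displacement curve
#'
#' MSD as a function of lag time for molecular mass centres of one
#' species, averaged over all molecules and all time origins (positions
#' are stored unwrapped, so no image bookkeeping is needed).
#'
#' @param traj An `elba_trajectory`.
#' @param ff The force field.
#' @param species Molecule species to track.
#' @param lateral If `TRUE`, use only x-y displacements.
#' @param max_lag_frac Longest lag as a fraction of the trajectory.
#' @return Data frame with `t` (ps) and `msd` (nm^2).
#' @export
msd_curve <- function(traj, ff = elba_forcefield(), species = "water",
                      lateral = FALSE, max_lag_frac = 0.5) {
  com <- .com_traj(traj, ff, species)
  if (lateral) com <- com[1:2, , , drop = FALSE]
  nf <- dim(com)[3]
  dt <- stats::median(diff(traj$time))
  lags <- seq_len(max(1, floor(nf * max_lag_frac)))
  msd <- vapply(lags, function(l) {
    d <- com[, , (1 + l):nf, drop = FALSE] - com[, , 1:(nf - l), drop = FALSE]
    mean(colSums(matrix(d^2, nrow = dim(com)[1])))
  }, numeric(1))
  data.frame(t = lags * dt, msd = msd)
}

#' Diffusion coefficient from an MSD fit
#'
#' Least-squares slope of the MSD curve over a lag window, divided by
#' `2 * dim` (`dim = 3` for bulk, 2 for lateral diffusion).
#'
#' @inheritParams msd_curve
#' @param fit_frac Fraction `c(lo, hi)` of the lag range used in the fit.
#' @return List with `D_nm2_ps`, `D_m2_s`, `D_cm2_s` and the `msd` curve.
#' @export
diffusion_coefficient <- function(traj, ff = elba_forcefield(),
                                  species = "water", lateral = FALSE,
                                  fit_frac = c(0.2, 0.9),
                                  max_lag_frac = 0.5) {
  m <- msd_curve(traj, ff, species, lateral, max_lag_frac)
  tmax <- max(m$t)
  sel <- m$t >= fit_frac[1] * tmax & m$t <= fit_frac[2] * tmax
  slope <- stats::coef(stats::lm(msd ~ t, data = m[sel, ]))[["t"]]
  ndim <- if (lateral) 2 else 3
  D <- slope / (2 * ndim)                  # nm^2/ps
  list(D_nm2_ps = D, D_m2_s = D * 1e-6, D_cm2_s = D * 1e-2, msd = m)
}

#' Lipid lateral diffusion coefficient
#'
#' `D_L = < sum_i |r_i(t0 + t) - r_i(t0)|^2 > / (4 N t)` over the lateral
#' mass-centre displacements of all lipids, averaged over a set of time
#' origins (monolayer drift is removed during the run, so no further
#' correction is applied).
#'
#' @inheritParams msd_curve
#' @param t_meas Measurement time, ps.
#' @param n_origins Number of evenly spaced origins.
#' @return List with `D_nm2_ps`, `D_cm2_s`, `D_nm2_us`, `t_meas` and
#'   `n_origins`.
#' @export
lateral_diffusion <- function(traj, ff = elba_forcefield(),
                              t_meas = NULL, n_origins = 26) {
  sp <- setdiff(unique(traj$species), "water")[1]
  com <- .com_traj(traj, ff, sp)[1:2, , , drop = FALSE]
  nf <- dim(com)[3]
  dt <- stats::median(diff(traj$time))
  if (is.null(t_meas)) t_meas <- (nf - 1) * dt / 2
  lag <- max(1, round(t_meas / dt))
  if (lag >= nf) stop("t_meas exceeds trajectory length")
  origins <- unique(round(seq(1, nf - lag, length.out = n_origins)))
  acc <- 0
  for (o in origins) {
    d <- com[, , o + lag] - com[, , o]
    acc <- acc + mean(colSums(matrix(d^2, nrow = 2)))
  }
  msd <- acc / length(origins)
  D <- msd / (4 * lag * dt)                # nm^2/ps
  list(D_nm2_ps = D, D_cm2_s = D * 1e-2, D_nm2_us = D * 1e6,
       t_meas = lag * dt, n_origins = length(origins))
}

#' Water permeability from spontaneous crossings
#'
#' Counts water molecules that fully traverse the bilayer (hysteresis
#' rule: a crossing requires passage from one bulk region through the
#' membrane into the opposite bulk region; interfacial recrossings do
#' not count) and converts the average unidirectional flux to a
#' permeability coefficient by Fick's first law:
#' `P = (N_cross/2) / (t A dc)`.
#'
#' @inheritParams msd_curve
#' @param bounds Membrane boundary planes `c(lower, upper)` in
#'   bilayer-centred z (nm); default: mean ester-site |z| +/- `margin`.
#' @param margin Hysteresis margin added outside the ester planes, nm.
#' @param dc Bulk water concentration, molecules/nm^3.
#' @return List with `P_cm_s`, `P_nm_ps`, `n_cross`, `t_ps`, `area_nm2`.
#' @export
water_permeability <- function(traj, ff = elba_forcefield(), bounds = NULL,
                               margin = 0.3, dc = 33.4) {
  mass <- ff$sites$mass[traj$type]
  nf <- .n_frames(traj)
  wsel <- which(traj$species == "water")
  if (!length(wsel)) stop("no water in trajectory")
  # bilayer-centred z for every site and frame
  if (is.null(bounds)) {
    est <- which(traj$site_name %in% c("ester_a", "ester_b"))
    if (!length(est)) stop("no ester sites; give bounds explicitly")
    ez <- 0
    for (f in seq_len(nf)) {
      zs <- .slab_z(traj, f, mass) - traj$box[f, 3] / 2
      ez <- ez + mean(abs(zs[est]))
    }
    ez <- ez / nf
    bounds <- c(-(ez + margin), ez + margin)
  }
  state <- integer(length(wsel))           # +1 upper bulk, -1 lower, 0 inside
  n_cross <- 0L
  for (f in seq_len(nf)) {
    zw <- .slab_z(traj, f, mass)[wsel] - traj$box[f, 3] / 2
    reg <- ifelse(zw > bounds[2], 1L, ifelse(zw < bounds[1], -1L, 0L))
    if (f == 1) {
      state <- reg
    } else {
      crossed <- reg != 0L & state != 0L & reg != state
      n_cross <- n_cross + sum(crossed)
      state[reg != 0L] <- reg[reg != 0L]
    }
  }
  t_ps <- max(traj$time) - min(traj$time)
  area <- mean(traj$box[, 1] * traj$box[, 2])
  P <- (n_cross / 2) / (t_ps * area * dc)  # nm/ps
  list(P_cm_s = P * 1e5, P_nm_ps = P, n_cross = n_cross,
       t_ps = t_ps, area_nm2 = area)
}
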