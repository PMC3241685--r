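# Molecule templates and system construction.
#
# Lipids are 15 CG sites: choline/amine (1), phosphate (2), glycerol (3),
# ester sn-1 (4) + 5 tail sites (5-9), ester sn-2 (10) + 5 tail sites
# (11-15).  Electrons and atoms are partitioned per site so that the
# molecular totals match the molecular formulas: DOPC C44H84NO8P
# (138 atoms, 434 electrons), DSPC C44H88NO8P (438 e-), DOPE C41H78NO8P
# (410 e-), water H2O (10 e-).

.lipid_species <- c("DOPC", "DSPC", "DOPE")

# Per-site electron/atom partitions.  Head = choline (N(CH3)3CH2CH2) or
# amine (NH3CH2CH2); phosphate = PO4; glycerol = C3H5 backbone + 2 ester
# ether oxygens; ester = carbonyl C=O + first two chain carbons; tail
# sites = consecutive carbon triplets with their hydrogens (the
# cis-unsaturated triplets of the oleoyl chains carry two fewer H).
.site_partition <- function(species) {
  head <- if (species == "DOPE") c(e = 26, a = 10) else c(e = 50, a = 19)
  tails <- if (species == "DSPC")
    list(e = c(24, 24, 24, 24, 25), a = c(9, 9, 9, 9, 10))
  else
    list(e = c(24, 23, 23, 24, 25), a = c(9, 8, 8, 9, 10))
  list(head = head,
       phosphate = c(e = 47, a = 5),
       glycerol  = c(e = 39, a = 10),
       ester     = c(e = 30, a = 8),
       tails     = tails)
}

#' Build a molecule template
#'
#' Constructs the bonded topology of one molecule of the given species:
#' ordered site list with types and per-site electron/atom bookkeeping,
#' bonds (reference lengths from [reference_bond_length()]), angles
#' (cosine-harmonic; DOPC/DOPE carry the cis-kink reference angle on the
#' triplet centred on the second tail site of each tail, DSPC the saturated
#' angle everywhere), and the dipole orientation restraints (glycerol
#' dipole along the glycerol-to-phosphate bond, each ester dipole along the
#' ester-to-adjacent-tail bond).  DOPE replaces the choline site by the
#' amine type.
#'
#' @param species One of `"water"`, `"DOPC"`, `"DSPC"`, `"DOPE"`.
#' @param ff An [elba_forcefield()].
#' @return An `elba_template`: list with `species`, `sites` (data frame:
#'   `name`, `type`, `electrons`, `atoms`), `bonds` (`i`, `j`, `kb`, `r0`),
#'   `angles` (`i`, `j`, `k`, `ka`, `theta0` \[deg\]), `restraints`
#'   (`site`, `ref_from`, `ref_to`, `kd`).
#' @examples
#' ff <- elba_forcefield()
#' tpl <- make_template("DOPC", ff)
#' sum(tpl$sites$electrons)  # 434
#' @export
make_template <- function(species, ff) {
  species <- match.arg(species, c("water", .lipid_species))
  if (species == "water") {
    tpl <- list(species = "water",
                sites = data.frame(name = "water", type = "water",
                                   electrons = 10, atoms = 3,
                                   stringsAsFactors = FALSE),
                bonds = data.frame(i = integer(), j = integer(),
                                   kb = numeric(), r0 = numeric()),
                angles = data.frame(i = integer(), j = integer(),
                                    k = integer(), ka = numeric(),
                                    theta0 = numeric()),
                restraints = data.frame(site = integer(),
                                        ref_from = integer(),
                                        ref_to = integer(), kd = numeric()))
    class(tpl) <- "elba_template"
    return(tpl)
  }

  part <- .site_partition(species)
  head_type <- if (species == "DOPE") "amine" else "choline"
  types <- c(head_type, "phosphate", "glycerol",
             "ester", rep("tail", 5), "ester", rep("tail", 5))
  names_ <- c("head", "phosphate", "glycerol",
              "ester_a", paste0("tail_a", 1:5),
              "ester_b", paste0("tail_b", 1:5))
  electrons <- c(part$head["e"], part$phosphate["e"], part$glycerol["e"],
                 part$ester["e"], part$tails$e,
                 part$ester["e"], part$tails$e)
  atoms <- c(part$head["a"], part$phosphate["a"], part$glycerol["a"],
             part$ester["a"], part$tails$a,
             part$ester["a"], part$tails$a)

  bond_pairs <- rbind(c(1, 2), c(2, 3), c(3, 4),
                      cbind(4:8, 5:9),
                      c(3, 10), cbind(10:14, 11:15))
  kb <- ff$bonded$kb
  r0 <- apply(bond_pairs, 1, function(b)
    reference_bond_length(ff, types[b[1]], types[b[2]]))
  bonds <- data.frame(i = bond_pairs[, 1], j = bond_pairs[, 2],
                      kb = kb, r0 = r0)

  th_sat  <- ff$bonded$theta_saturated
  th_kink <- if (species == "DSPC") th_sat else ff$bonded$theta_unsaturated
  ang <- rbind(
    c(1, 2, 3,  ff$bonded$theta_head),
    c(2, 3, 4,  ff$bonded$theta_branch),
    c(2, 3, 10, ff$bonded$theta_branch),
    c(3, 4, 5,  th_sat),
    c(4, 5, 6,  th_sat),
    c(5, 6, 7,  th_kink),    # triplet centred on 2nd tail site
    c(6, 7, 8,  th_sat),
    c(7, 8, 9,  th_sat),
    c(3, 10, 11, th_sat),
    c(10, 11, 12, th_sat),
    c(11, 12, 13, th_kink),
    c(12, 13, 14, th_sat),
    c(13, 14, 15, th_sat))
  angles <- data.frame(i = ang[, 1], j = ang[, 2], k = ang[, 3],
                       ka = ff$bonded$ka, theta0 = ang[, 4])

  restraints <- data.frame(site = c(3, 4, 10),
                           ref_from = c(3, 4, 10),
                           ref_to = c(2, 5, 11),
                           kd = ff$bonded$kd)

  tpl <- list(species = species,
              sites = data.frame(name = names_, type = types,
                                 electrons = unname(electrons),
                                 atoms = unname(atoms),
                                 stringsAsFactors = FALSE),
              bonds = bonds, angles = angles, restraints = restraints)
  class(tpl) <- "elba_template"
  tpl
}

#' @export
print.elba_template <- function(x, ...) {
  cat("elba_template:", x$species, "-", nrow(x$sites), "sites,",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$restraints), "dipole restraints\n")
  cat("electrons:", sum(x$sites$electrons),
      " atoms:", sum(x$sites$atoms), "\n")
  invisible(x)
}

# ---- system assembly ------------------------------------------------------

.new_system <- function(ff, box) {
  list(pos = matrix(numeric(), 0, 3), vel = matrix(numeric(), 0, 3),
       u = matrix(numeric(), 0, 3), omega = matrix(numeric(), 0, 3),
       type = integer(), mol = integer(), leaflet = integer(),
       group = integer(), species = character(), site_name = character(),
       electrons = numeric(),
       bonds = matrix(numeric(), 0, 4,
                      dimnames = list(NULL, c("i", "j", "kb", "r0"))),
       angles = matrix(numeric(), 0, 5,
                       dimnames = list(NULL, c("i", "j", "k", "ka", "theta0"))),
       restraints = matrix(numeric(), 0, 4,
                           dimnames = list(NULL, c("site", "ref_from",
                                                   "ref_to", "kd"))),
       box = box, time = 0, ff_checksum = ff$checksum)
}

.append_molecules <- function(sys, tpl, ff, pos_list, u_list, leaflet) {
  tidx <- match(tpl$sites$type, ff$sites$name)
  ns <- nrow(tpl$sites)
  nmol <- length(pos_list)
  n_old <- nrow(sys$pos)
  mol0 <- if (length(sys$mol)) max(sys$mol) else 0L
  grp <- if (tpl$species == "water") 0L else 1L

  sys$pos <- rbind(sys$pos, do.call(rbind, pos_list))
  dimnames(sys$pos) <- NULL
  sys$u <- rbind(sys$u, do.call(rbind, u_list))
  dimnames(sys$u) <- NULL
  sys$type <- c(sys$type, rep(tidx, nmol))
  sys$mol <- c(sys$mol, rep(mol0 + seq_len(nmol), each = ns))
  sys$leaflet <- c(sys$leaflet, rep(leaflet, each = ns))
  sys$group <- c(sys$group, rep(grp, ns * nmol))
  sys$species <- c(sys$species, rep(tpl$species, ns * nmol))
  sys$site_name <- c(sys$site_name, rep(tpl$sites$name, nmol))
  sys$electrons <- c(sys$electrons, rep(tpl$sites$electrons, nmol))
  sys$vel <- rbind(sys$vel, matrix(0, ns * nmol, 3))
  sys$omega <- rbind(sys$omega, matrix(0, ns * nmol, 3))

  if (nrow(tpl$bonds)) {
    offs <- n_old + (seq_len(nmol) - 1L) * ns
    for (o in offs) {
      sys$bonds <- rbind(sys$bonds, cbind(tpl$bonds$i + o, tpl$bonds$j + o,
                                          tpl$bonds$kb, tpl$bonds$r0))
      sys$angles <- rbind(sys$angles,
                          cbind(tpl$angles$i + o, tpl$angles$j + o,
                                tpl$angles$k + o, tpl$angles$ka,
                                tpl$angles$theta0))
      sys$restraints <- rbind(sys$restraints,
                              cbind(tpl$restraints$site + o,
                                    tpl$restraints$ref_from + o,
                                    tpl$restraints$ref_to + o,
                                    tpl$restraints$kd))
    }
  }
  sys
}

# Maxwell-Boltzmann velocities at T, net momentum removed, then rescaled to
# the exact target temperature; angular velocities are drawn in the plane
# perpendicular to each dipole axis.
.thermalise <- function(sys, ff, temperature) {
  n <- nrow(sys$pos)
  mass <- ff$sites$mass[sys$type]
  v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(.kB * temperature / mass)
  pm <- colSums(v * mass) / sum(mass)
  v <- sweep(v, 2, pm)
  ke <- 0.5 * sum(mass * rowSums(v^2))
  t_inst <- 2 * ke / ((3 * n - 3) * .kB)
  v <- v * sqrt(temperature / t_inst)
  sys$vel <- v

  inertia <- ff$sites$inertia[sys$type]
  has_dip <- ff$sites$dipole[sys$type] > 0
  om <- matrix(0, n, 3)
  if (any(has_dip)) {
    for (i in which(has_dip)) {
      u <- sys$u[i, ]
      e1 <- .perp_unit(u)
      e2 <- .cross3(u, e1)
      sd_w <- sqrt(.kB * temperature / inertia[i])
      om[i, ] <- stats::rnorm(1, 0, sd_w) * e1 + stats::rnorm(1, 0, sd_w) * e2
    }
  }
  sys$omega <- om
  sys
}

.perp_unit <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- .cross3(u, a)
  v / sqrt(sum(v^2))
}

.random_unit <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Build a bulk water box
#'
#' Places `n` dipolar water sites on a simple cubic lattice in a cubic box
#' sized to the requested mass density, with uniformly random dipole
#' orientations and Maxwell-Boltzmann translational/rotational velocities
#' at the requested temperature (zero net momentum, exact initial kinetic
#' temperature).  Two builds with the same seed are identical.
#'
#' @param n Number of water sites (>= 8).  Perfect cubes tile the lattice
#'   exactly; otherwise trailing lattice points stay empty and anneal out
#'   during equilibration.
#' @param density Target mass density, g/cm^3.
#' @param temperature Temperature, K.
#' @param ff An [elba_forcefield()].
#' @param seed Integer seed (set to `NULL` to use the current RNG state).
#' @return An `elba_system` (see package vignette for the field list).
#' @examples
#' sys <- build_water_box(64, seed = 1)
#' @export
build_water_box <- function(n, density = 0.996, temperature = 303,
                            ff = elba_forcefield(), seed = NULL) {
  if (n < 8) stop("build_water_box: need n >= 8")
  if (!is.null(seed)) set.seed(seed)
  m_w <- .ff_type_row(ff, "water")$mass_phys
  vol <- n * m_w * .AMU_NM3 / density      # nm^3
  L <- vol^(1 / 3)
  m <- ceiling(n^(1 / 3) - 1e-9)
  a <- L / m
  g <- expand.grid(x = 0:(m - 1), y = 0:(m - 1), z = 0:(m - 1))
  pos <- (as.matrix(g)[seq_len(n), , drop = FALSE] + 0.5) * a

  tpl <- make_template("water", ff)
  sys <- .new_system(ff, box = c(L, L, L))
  u <- .random_unit(n)
  sys <- .append_molecules(sys, tpl, ff,
                           pos_list = lapply(seq_len(n), function(i)
                             pos[i, , drop = FALSE]),
                           u_list = lapply(seq_len(n), function(i)
                             u[i, , drop = FALSE]),
                           leaflet = rep(NA_integer_, n))
  sys <- .thermalise(sys, ff, temperature)
  class(sys) <- "elba_system"
  sys
}

# Straight-chain lipid conformation pointing its tails toward -dirz;
# head site at the local origin (caller translates).
.lipid_conformation <- function(tpl, ff, dirz = 1, tail_dx = 0.35) {
  r0 <- stats::setNames(tpl$bonds$r0, paste(tpl$bonds$i, tpl$bonds$j))
  b <- function(i, j) unname(r0[paste(min(i, j), max(i, j))])
  z <- numeric(15)
  z[1] <- 0
  z[2] <- z[1] - b(1, 2)
  z[3] <- z[2] - b(2, 3)
  z[4] <- z[3] - b(3, 4) * 0.7
  for (k in 5:9) z[k] <- z[k - 1] - b(k - 1, k) * 0.95
  z[10] <- z[3] - b(3, 10) * 0.7
  for (k in 11:15) z[k] <- z[k - 1] - b(k - 1, k) * 0.95
  x <- numeric(15)
  x[c(4, 5:9)] <- -tail_dx / 2
  x[c(10, 11:15)] <- tail_dx / 2
  cbind(x, 0, dirz * z)
}

.init_lipid_dipoles <- function(tpl, pos) {
  u <- matrix(0, nrow(pos), 3)
  for (r in seq_len(nrow(tpl$restraints))) {
    s <- tpl$restraints$site[r]
    v <- pos[tpl$restraints$ref_to[r], ] - pos[tpl$restraints$ref_from[r], ]
    u[s, ] <- v / sqrt(sum(v^2))
  }
  u
}

.default_area <- function(species, temperature) {
  # starting lattice areas (A^2 per lipid), by species/phase
  if (species == "DSPC" && temperature < 310) 48 else
    if (species == "DSPC") 62 else if (species == "DOPE") 60 else 67
}

#' Build a preassembled hydrated bilayer
#'
#' Places two opposed leaflets of straight-conformation lipids on square
#' lattices normal to z (tails inward), with water slabs at the requested
#' hydration on both sides.  Headgroup charges are carried by the types;
#' restrained dipoles start aligned with their reference bonds and water
#' dipoles uniformly at random.  Initial box area matches the target area
#' per lipid.
#'
#' @param species `"DOPC"`, `"DSPC"` or `"DOPE"`.
#' @param n_lipids Total lipid count (even; split into two equal leaflets;
#'   each leaflet count should be a perfect square for an exact lattice).
#' @param hydration Waters per lipid.
#' @param temperature Temperature, K (also selects the default starting
#'   area per lipid).
#' @param area_per_lipid Starting projected area per lipid, Angstrom^2.
#' @param ff An [elba_forcefield()].
#' @param seed Integer seed.
#' @return An `elba_system`.
#' @examples
#' sys <- build_bilayer("DOPC", 8, hydration = 10, seed = 1)
#' @export
build_bilayer <- function(species, n_lipids, hydration = 33.06,
                          temperature = 303,
                          area_per_lipid = .default_area(species, temperature),
                          ff = elba_forcefield(), seed = NULL) {
  if (n_lipids %% 2 != 0) stop("build_bilayer: n_lipids must be even")
  if (!is.null(seed)) set.seed(seed)
  tpl <- make_template(species, ff)
  n_leaf <- n_lipids / 2
  nx <- ceiling(sqrt(n_leaf))
  ny <- ceiling(n_leaf / nx)
  apl <- area_per_lipid / 100            # nm^2
  Lx <- nx * sqrt(apl); Ly <- ny * sqrt(apl)
  # square interface
  Lx <- Ly <- sqrt(n_leaf * apl)
  ax <- Lx / nx; ay <- Ly / ny

  conf <- .lipid_conformation(tpl, ff)
  lip_len <- max(conf[, 3]) - min(conf[, 3])
  # compress the straight-chain conformation along z so the leaflet
  # thickness matches the expected lipid volume at the target area;
  # otherwise chains contract on relaxation and open a vacuum slab at
  # the midplane that takes very long to close under pressure coupling
  m_lip <- sum(ff$sites$mass_phys[match(tpl$sites$type, ff$sites$name)])
  v_lip <- m_lip * .AMU_NM3 / 0.95          # nm^3 at ~0.95 g/cm^3
  zscale <- min(1, (v_lip / apl) / lip_len)
  lip_len <- lip_len * zscale
  half <- lip_len + 0.15    # head-site z from centre; tail ends at +/-0.15
  wpad <- 0.35              # clearance between head sites and first water
  n_w <- round(hydration * n_lipids)
  m_w <- .ff_type_row(ff, "water")$mass_phys
  vol_w <- n_w * m_w * .AMU_NM3 / 0.996
  Lz <- 2 * (half + wpad) + vol_w / (Lx * Ly)
  box <- c(Lx, Ly, Lz)
  zmid <- Lz / 2

  pos_list <- list(); u_list <- list(); leaf <- integer()
  mcount <- 0
  for (lf in 0:1) {
    dirz <- if (lf == 0) 1 else -1
    ztop <- zmid + dirz * half
    placed <- 0
    for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
      if (placed >= n_leaf) next
      placed <- placed + 1; mcount <- mcount + 1
      base <- .lipid_conformation(tpl, ff, dirz = dirz)
      base[, 3] <- base[, 3] * zscale
      off <- c((ix - 0.5) * ax + 0.05 * ax * (lf * 2 - 1),
               (iy - 0.5) * ay, ztop)
      p <- sweep(base, 2, off, "+")
      pos_list[[mcount]] <- p
      u_list[[mcount]] <- .init_lipid_dipoles(tpl, p)
      leaf <- c(leaf, lf)
    }
  }

  sys <- .new_system(ff, box)
  sys <- .append_molecules(sys, tpl, ff, pos_list, u_list, leaf)

  # water slabs above and below, split evenly, on jittered sc lattices
  if (n_w > 0) {
    wtpl <- make_template("water", ff)
    slab_lz <- (Lz - 2 * (half + wpad)) / 2
    nw_half <- c(ceiling(n_w / 2), floor(n_w / 2))
    zlo <- c(zmid + half + wpad, zmid - half - wpad - slab_lz)
    wpos <- list(); wu <- list(); wi <- 0
    for (s in 1:2) {
      nws <- nw_half[s]
      if (nws == 0) next
      # lattice spacing from slab volume
      a3 <- (Lx * Ly * slab_lz) / nws
      a <- a3^(1 / 3)
      mx <- max(1, floor(Lx / a)); my <- max(1, floor(Ly / a))
      mz <- ceiling(nws / (mx * my))
      g <- expand.grid(x = 0:(mx - 1), y = 0:(my - 1), z = 0:(mz - 1))
      g <- as.matrix(g)[seq_len(nws), , drop = FALSE]
      p <- cbind((g[, 1] + 0.5) * (Lx / mx),
                 (g[, 2] + 0.5) * (Ly / my),
                 zlo[s] + (g[, 3] + 0.5) * (slab_lz / mz))
      for (k in seq_len(nws)) {
        wi <- wi + 1
        wpos[[wi]] <- p[k, , drop = FALSE]
      }
    }
    uw <- .random_unit(wi)
    wu <- lapply(seq_len(wi), function(i) uw[i, , drop = FALSE])
    sys <- .append_molecules(sys, wtpl, ff, wpos, wu,
                             rep(NA_integer_, wi))
  }

  sys <- .thermalise(sys, ff, temperature)
  class(sys) <- "elba_system"
  sys
}

#' Build a random lipid/water dispersion
#'
#' Places lipids with random positions and orientations (straight
#' conformation), rejecting placements where any site comes closer than
#' `overlap_frac * sigma_ij` to an already placed site, then fills the
#' remaining space with water on a jittered lattice under the same
#' overlap criterion.  Used as the start of self-assembly runs.
#'
#' @inheritParams build_bilayer
#' @param total_density Initial overall mass density, g/cm^3 (the gap to
#'   liquid density closes during pressure-coupled equilibration).
#' @param overlap_frac Overlap rejection threshold as a fraction of the
#'   mixed Lennard-Jones sigma.
#' @param compact Uniform scaling applied to the lipid conformation at
#'   placement; compacted lipids pack at useful densities and re-expand
#'   during relaxation.
#' @param max_tries Placement attempts per lipid before giving up.
#' @return An `elba_system`.
#' @export
build_random_dispersion <- function(species, n_lipids, hydration = 20,
                                    temperature = 303, total_density = 0.65,
                                    overlap_frac = 0.8, compact = 0.7,
                                    max_tries = 2000,
                                    ff = elba_forcefield(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- make_template(species, ff)
  n_w <- round(hydration * n_lipids)
  masses <- ff$sites$mass_phys
  m_lip <- sum(masses[match(tpl$sites$type, ff$sites$name)])
  m_w <- .ff_type_row(ff, "water")$mass_phys
  vol <- (n_lipids * m_lip + n_w * m_w) * .AMU_NM3 / total_density
  L <- vol^(1 / 3)
  box <- c(L, L, L)

  sig <- ff$sites$sigma
  tidx_tpl <- match(tpl$sites$type, ff$sites$name)
  widx <- match("water", ff$sites$name)

  placed_pos <- matrix(numeric(), 0, 3)
  placed_type <- integer()
  min_image_d2 <- function(p, q) {
    d <- sweep(q, 2, p)
    d <- d - round(sweep(d, 2, box, "/")) * rep(box, each = nrow(d))
    rowSums(d^2)
  }
  overlaps <- function(p, ti) {
    if (nrow(placed_pos) == 0) return(FALSE)
    d2 <- min_image_d2(p, placed_pos)
    thr <- (overlap_frac * (sig[ti] + sig[placed_type]) / 2)^2
    any(d2 < thr)
  }

  rot_z <- function(v, axis, ang) {
    # Rodrigues rotation
    k <- axis / sqrt(sum(axis^2))
    v * cos(ang) + .cross3(k, v) * sin(ang) + k * sum(k * v) * (1 - cos(ang))
  }

  pos_list <- list(); u_list <- list()
  base <- .lipid_conformation(tpl, ff) * compact
  base <- sweep(base, 2, colMeans(base))
  for (m in seq_len(n_lipids)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      axis <- .random_unit(1)[1, ]
      ang <- stats::runif(1, 0, 2 * pi)
      p <- t(apply(base, 1, rot_z, axis = axis, ang = ang))
      cen <- stats::runif(3, 0, L)
      p <- sweep(p, 2, cen, "+")
      bad <- FALSE
      for (k in seq_len(15)) {
        if (overlaps(p[k, ], tidx_tpl[k])) { bad <- TRUE; break }
      }
      if (!bad) {
        pos_list[[m]] <- p
        u_list[[m]] <- .init_lipid_dipoles(tpl, p)
        placed_pos <- rbind(placed_pos, p)
        placed_type <- c(placed_type, tidx_tpl)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("build_random_dispersion: could not place lipid ", m,
                  "; lower the density or overlap threshold")
  }

  sys <- .new_system(ff, box)
  sys <- .append_molecules(sys, tpl, ff, pos_list, u_list,
                           rep(NA_integer_, n_lipids))

  # water fill on a jittered lattice
  if (n_w > 0) {
    mlat <- ceiling((2 * n_w)^(1 / 3))
    a <- L / mlat
    g <- expand.grid(x = 0:(mlat - 1), y = 0:(mlat - 1), z = 0:(mlat - 1))
    cand <- (as.matrix(g) + 0.5) * a
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    wpos <- list(); wi <- 0
    for (k in seq_len(nrow(cand))) {
      if (wi >= n_w) break
      p <- cand[k, ] + stats::runif(3, -0.1, 0.1) * a
      p <- p %% box
      if (!overlaps(p, widx)) {
        wi <- wi + 1
        wpos[[wi]] <- matrix(p, 1, 3)
        placed_pos <- rbind(placed_pos, p)
        placed_type <- c(placed_type, widx)
      }
    }
    if (wi < n_w)
      stop("build_random_dispersion: only ", wi, " of ", n_w,
           " waters placed; lower the density")
    uw <- .random_unit(wi)
    sys <- .append_molecules(sys, make_template("water", ff), ff, wpos,
                             lapply(seq_len(wi), function(i)
                               uw[i, , drop = FALSE]),
                             rep(NA_integer_, wi))
  }

  sys <- .thermalise(sys, ff, temperature)
  class(sys) <- "elba_system"
  sys
}

#' @export
print.elba_system <- function(x, ...) {
  n <- nrow(x$pos)
  nmol <- length(unique(x$mol))
  cat("elba_system:", n, "sites,", nmol, "molecules, box",
      paste(signif(x$box, 5), collapse = " x "), "nm, t =",
      x$time, "ps\n")
  print(table(x$species[!duplicated(x$mol)]))
  invisible(x)
}
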