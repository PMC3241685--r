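#' Read an ELBA force-field parameter file
#'
#' Parses the plain-text parameter file holding the per-type nonbonded
#' parameters, hydrogen-bond epsilon scalings, bonded rigidities and
#' reference angles, and the cutoff scheme.  All numeric force-field values
#' live in this file, never in code; the file header records the functional
#' form conventions (half prefactors, cosine-harmonic angles,
#' `1 - cos` restraints) so they can be audited without reading the source.
#'
#' @param file Path to a parameter file.  The default is the force field
#'   shipped with the package.
#' @return An object of class `elba_forcefield`: a list with elements
#'   `sites` (data frame: name, sigma \[nm\], epsilon \[kJ/mol\], mass
#'   \[amu\], charge \[e\], dipole \[D\], inertia \[amu nm^2\]), `hbond`
#'   (data frame of scaled pairs), `bonded` (named list: `kb`, `ka`, `kd`,
#'   reference angles in degrees), `cutoffs` (named list: `cutoff_ww`,
#'   `cutoff_other`, `switch_fraction`) and `checksum` (md5 of the file,
#'   embedded in every output for provenance).
#' @examples
#' ff <- elba_forcefield()
#' ff$sites
#' @export
elba_forcefield <- function(file = system.file("extdata", "elba-ff.txt",
                                               package = "elbamd")) {
  if (!file.exists(file)) stop("parameter file not found: ", file)
  raw <- readLines(file)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]

  section <- NA_character_
  sites <- list(); hbond <- list(); bonded <- list(); cutoffs <- list()
  for (ln in raw) {
    if (grepl("^\\[", ln)) {
      section <- gsub("[][]", "", ln)
      next
    }
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (is.na(section)) stop("parameter line outside any section: ", ln)
    switch(section,
      sites = {
        if (length(tok) != 8L)
          stop("malformed [sites] line (need 8 fields): ", ln)
        sites[[length(sites) + 1L]] <- data.frame(
          name = tok[1], sigma = as.numeric(tok[2]),
          epsilon = as.numeric(tok[3]), mass = as.numeric(tok[4]),
          charge = as.numeric(tok[5]), dipole = as.numeric(tok[6]),
          inertia = as.numeric(tok[7]), mass_phys = as.numeric(tok[8]),
          stringsAsFactors = FALSE)
      },
      hbond = {
        if (length(tok) != 3L)
          stop("malformed [hbond] line (need 3 fields): ", ln)
        hbond[[length(hbond) + 1L]] <- data.frame(
          type_i = tok[1], type_j = tok[2], s = as.numeric(tok[3]),
          stringsAsFactors = FALSE)
      },
      bonded  = {
        v <- suppressWarnings(as.numeric(tok[2]))
        bonded[[tok[1]]] <- if (is.na(v)) tok[2] else v
      },
      cutoffs = cutoffs[[tok[1]]] <- as.numeric(tok[2]),
      stop("unknown section [", section, "]")
    )
  }
  sites <- do.call(rbind, sites)
  hbond <- if (length(hbond)) do.call(rbind, hbond) else
    data.frame(type_i = character(), type_j = character(), s = numeric())

  stopifnot(all(sites$sigma > 0), all(sites$epsilon > 0),
            all(sites$mass > 0), all(sites$dipole >= 0),
            all(hbond$s >= 1))
  if (any(sites$dipole > 0 & sites$inertia <= 0))
    stop("every dipole-carrying type needs a positive moment of inertia")
  with(cutoffs, stopifnot(cutoff_ww > 0, cutoff_other > 0,
                          switch_fraction > 0, switch_fraction < 1))

  ff <- list(sites = sites, hbond = hbond, bonded = bonded,
             cutoffs = cutoffs, file = file,
             checksum = unname(tools::md5sum(file)))
  class(ff) <- "elba_forcefield"
  ff
}

#' @export
print.elba_forcefield <- function(x, ...) {
  cat("ELBA force field (", nrow(x$sites), " site types, ",
      nrow(x$hbond), " hydrogen-bond scalings)\n", sep = "")
  cat("file:", x$file, "\nchecksum:", x$checksum, "\n")
  print(x$sites, row.names = FALSE)
  invisible(x)
}

.ff_type_row <- function(ff, type) {
  i <- match(type, ff$sites$name)
  if (is.na(i)) stop("unknown site type: ", type)
  ff$sites[i, ]
}

.hb_scaling <- function(ff, ti, tj) {
  hb <- ff$hbond
  hit <- (hb$type_i == ti & hb$type_j == tj) |
         (hb$type_i == tj & hb$type_j == ti)
  if (any(hit)) hb$s[hit][1] else 1
}

#' Lorentz-Berthelot mixing with hydrogen-bond scaling
#'
#' Combines two site types into the pair parameters used by every nonbonded
#' interaction: `sigma_ij` is the arithmetic mean, `epsilon_ij` the
#' geometric mean multiplied by the hydrogen-bond scaling `s_ij` (`s_ij > 1`
#' only for the donor-acceptor pairs listed in the parameter file, 1
#' otherwise).  Water-water pairs use the short cutoff; every other pair the
#' long one.  The dipole-dipole switch radius is `switch_fraction * cutoff`.
#'
#' @param ff An [elba_forcefield()].
#' @param type_i,type_j Site type names.
#' @return List with `sigma_ij` (nm), `epsilon_ij` (kJ/mol), `s_ij`,
#'   `cutoff` (nm) and `switch_radius` (nm).
#' @examples
#' ff <- elba_forcefield()
#' mix_params(ff, "choline", "water")$sigma_ij   # 0.41
#' @export
mix_params <- function(ff, type_i, type_j) {
  ri <- .ff_type_row(ff, type_i); rj <- .ff_type_row(ff, type_j)
  s <- .hb_scaling(ff, type_i, type_j)
  cutoff <- if (type_i == "water" && type_j == "water")
    ff$cutoffs$cutoff_ww else ff$cutoffs$cutoff_other
  list(sigma_ij   = (ri$sigma + rj$sigma) / 2,
       epsilon_ij = s * sqrt(ri$epsilon * rj$epsilon),
       s_ij       = s,
       cutoff     = cutoff,
       switch_radius = ff$cutoffs$switch_fraction * cutoff)
}

#' Reference bond length from the two Lennard-Jones diameters
#'
#' Bonded reference lengths are not free parameters: they are derived from
#' the Lennard-Jones diameters of the two bonded sites as the arithmetic
#' mean `r0 = (sigma_i + sigma_j)/2`, the same combination used for the
#' nonbonded `sigma_ij`.
#'
#' @inheritParams mix_params
#' @return Reference bond length in nm.
#' @export
reference_bond_length <- function(ff, type_i, type_j) {
  (.ff_type_row(ff, type_i)$sigma + .ff_type_row(ff, type_j)$sigma) / 2
}

#' Shifted-force Lennard-Jones interaction
#'
#' The 12-6 Lennard-Jones potential in the Stoddard-Ford shifted-force
#' form: a term linear in `r` and a constant are added so that both the
#' energy and its first radial derivative vanish continuously at the
#' cutoff.  Beyond the cutoff both outputs are exactly zero.
#'
#' @param r Interparticle distance(s), nm (vectorised).
#' @param sigma,epsilon Lennard-Jones parameters (nm, kJ/mol).
#' @param cutoff Cutoff radius, nm.
#' @return List with `energy` (kJ/mol) and `force` (kJ/mol/nm), the radial
#'   force `-dU/dr` (positive = repulsive).
#' @export
lj_shifted_force <- function(r, sigma, epsilon, cutoff) {
  if (any(r <= 0)) stop("lj_shifted_force: r must be > 0")
  sr6  <- (sigma / r)^6
  sr12 <- sr6^2
  sc6  <- (sigma / cutoff)^6
  sc12 <- sc6^2
  e <- 4 * epsilon *
    (sr12 - sr6 + (6 * sc12 - 3 * sc6) * (r / cutoff)^2 - 7 * sc12 + 4 * sc6)
  f <- 4 * epsilon *
    (12 * sr12 / r - 6 * sr6 / r - 2 * (6 * sc12 - 3 * sc6) * r / cutoff^2)
  off <- r >= cutoff
  e[off] <- 0; f[off] <- 0
  list(energy = e, force = f)
}

# Cubic C1 switching function for dipole-dipole interactions:
# S = 1 for r <= rs, S(rc) = 0, S'(rs) = S'(rc) = 0.
.dd_switch <- function(r, rs, rc) {
  s <- rep(1, length(r)); ds <- rep(0, length(r))
  mid <- r > rs & r < rc
  if (any(mid)) {
    t <- r[mid]
    d3 <- (rc - rs)^3
    s[mid]  <- 1 - (t - rs)^2 * (3 * rc - rs - 2 * t) / d3
    ds[mid] <- -6 * (t - rs) * (rc - t) / d3
  }
  off <- r >= rc
  s[off] <- 0; ds[off] <- 0
  list(s = s, ds = ds)
}

#' Switched point dipole-dipole interaction
#'
#' Classical point-dipole interaction (relative permittivity 1) multiplied
#' by a C1 cubic switching function equal to 1 below the switch radius and
#' 0 at the cutoff.  The force includes the switch-derivative term; torques
#' are `mu x E` with the switched field.
#'
#' @param r_vec Separation vector `r_i - r_j` (from j to i), nm.
#' @param mu_i,mu_j Dipole moment vectors, Debye.
#' @param cutoff,switch_radius Truncation radii, nm.
#' @return List with `energy` (kJ/mol), `force_i` (force on site i,
#'   kJ/mol/nm; the force on j is its negative), `torque_i` and `torque_j`
#'   (kJ/mol).
#' @export
dipole_dipole <- function(r_vec, mu_i, mu_j, cutoff,
                          switch_radius = 0.9 * cutoff) {
  r <- sqrt(sum(r_vec^2))
  if (r == 0) stop("dipole_dipole: zero separation")
  zero <- list(energy = 0, force_i = c(0, 0, 0),
               torque_i = c(0, 0, 0), torque_j = c(0, 0, 0))
  if (r >= cutoff) return(zero)
  pi_ <- mu_i * .DEBYE; pj <- mu_j * .DEBYE   # e nm
  rhat <- r_vec / r
  a_i <- sum(pi_ * rhat); a_j <- sum(pj * rhat)
  dot <- sum(pi_ * pj)
  sw <- .dd_switch(r, switch_radius, cutoff)
  u0 <- .KE_COUL * (dot - 3 * a_i * a_j) / r^3
  f0 <- (3 * .KE_COUL / r^4) *
    ((dot - 5 * a_i * a_j) * rhat + a_j * pi_ + a_i * pj)
  e_field_j <- .KE_COUL * (3 * a_j * rhat - pj) / r^3  # field of j at i
  e_field_i <- .KE_COUL * (3 * a_i * rhat - pi_) / r^3
  list(energy   = sw$s * u0,
       force_i  = sw$s * f0 - sw$ds * u0 * rhat,
       torque_i = sw$s * .cross3(pi_, e_field_j),
       torque_j = sw$s * .cross3(pj, e_field_i))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Shifted-force Coulomb interaction
#'
#' Point-charge interaction through a relative permittivity of 1, with the
#' shifted-force correction: both the energy and the radial force vanish
#' continuously at the cutoff.
#'
#' @param q_i,q_j Charges, elementary charge units (vectorised over `r`).
#' @param r Distance(s), nm.
#' @param cutoff Cutoff radius, nm.
#' @return List with `energy` (kJ/mol) and radial `force` (kJ/mol/nm,
#'   positive = repulsive for like charges).
#' @export
coulomb_shifted_force <- function(q_i, q_j, r, cutoff) {
  if (any(r <= 0)) stop("coulomb_shifted_force: r must be > 0")
  k <- .KE_COUL * q_i * q_j
  e <- k * (1 / r - 1 / cutoff + (r - cutoff) / cutoff^2)
  f <- k * (1 / r^2 - 1 / cutoff^2)
  off <- r >= cutoff
  e[off] <- 0; f[off] <- 0
  list(energy = e, force = f)
}

#' Shifted-force charge-dipole interaction
#'
#' Classical charge-dipole interaction with the shifted-force correction
#' applied to the radial scalar factor (`1/r^2` is replaced by
#' `1/r^2 - 3/rc^2 + 2 r/rc^3`), so that the energy and its radial
#' derivative vanish at the cutoff while the angular structure is
#' untouched.  The torque on the dipole is `mu x E` with the shifted field.
#'
#' @param q Charge (e) on the site at `r_vec` relative to the dipole.
#' @param mu Dipole moment vector, Debye.
#' @param r_vec Separation vector from the dipole site to the charge site, nm.
#' @param cutoff Cutoff radius, nm.
#' @return List with `energy` (kJ/mol), `force_q` (force on the charged
#'   site; the dipole site gets the negative), and `torque_mu` (kJ/mol).
#' @export
charge_dipole <- function(q, mu, r_vec, cutoff) {
  r <- sqrt(sum(r_vec^2))
  if (r == 0) stop("charge_dipole: zero separation")
  zero <- list(energy = 0, force_q = c(0, 0, 0), torque_mu = c(0, 0, 0))
  if (r >= cutoff) return(zero)
  p <- mu * .DEBYE
  rhat <- r_vec / r
  a <- sum(p * rhat)
  g  <- 1 / r^2 - 3 / cutoff^2 + 2 * r / cutoff^3
  dg <- -2 / r^3 + 2 / cutoff^3
  k <- .KE_COUL * q
  e <- k * a * g
  f_q <- -k * (g * (p - a * rhat) / r + a * dg * rhat)
  torque <- -k * g * .cross3(p, rhat)
  list(energy = e, force_q = f_q, torque_mu = torque)
}

#' Harmonic bond stretching
#'
#' Hooke potential `U = (kb/2)(r - r0)^2` with the half prefactor
#' convention recorded in the parameter file.
#'
#' @param r Bond length(s), nm.
#' @param kb Rigidity, kJ/(mol nm^2).
#' @param r0 Reference length, nm.
#' @return List with `energy` (kJ/mol) and radial `force` (kJ/mol/nm,
#'   positive = pushing the sites apart).
#' @export
bond_energy <- function(r, kb, r0) {
  if (any(r <= 0)) stop("bond_energy: r must be > 0")
  list(energy = 0.5 * kb * (r - r0)^2, force = -kb * (r - r0))
}

#' Angle bending potential
#'
#' Two selectable conventions for the triplet i-j-k (j central): the
#' harmonic `U = (ka/2)(th - th0)^2` (the default used by the shipped
#' parameter set: it has genuine harmonic stiffness at a straight
#' reference angle, which the cosine form lacks) and the cosine-harmonic
#' `U = (ka/2)(cos th - cos th0)^2`.  Both gradients are evaluated
#' through the cosine derivative, which stays finite at 0 and 180
#' degrees where a bare `1/sin` formulation would be singular.
#'
#' @param r_i,r_j,r_k Site positions (length-3 vectors), nm.
#' @param ka Rigidity (kJ/mol/rad^2 for `"theta"`, kJ/mol for
#'   `"cosine"`).
#' @param theta0 Reference angle, degrees.
#' @param style `"theta"` or `"cosine"`.
#' @return List with `energy`, `theta` (degrees) and `grad`, a 3x3 matrix of
#'   forces on i, j, k (rows), kJ/mol/nm.
#' @export
angle_energy <- function(r_i, r_j, r_k, ka, theta0, style = "theta") {
  style <- match.arg(style, c("theta", "cosine"))
  a <- r_i - r_j; b <- r_k - r_j
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2))
  if (la == 0 || lb == 0) stop("angle_energy: degenerate bond vector")
  cth <- sum(a * b) / (la * lb)
  cth <- max(-1, min(1, cth))
  th0 <- theta0 * pi / 180
  if (style == "cosine") {
    e <- 0.5 * ka * (cth - cos(th0))^2
    pref <- ka * (cth - cos(th0))      # dU/dcos
  } else {
    th <- acos(cth)
    e <- 0.5 * ka * (th - th0)^2
    sth <- sin(th)
    # (th - th0)/sin(th) is finite as th -> th0 = pi; floor only guards
    # exact collinearity, where the cosine gradient vanishes anyway
    pref <- -ka * (th - th0) / max(sth, 1e-8)
  }
  dci <- (b / (la * lb)) - cth * a / la^2
  dck <- (a / (la * lb)) - cth * b / lb^2
  g <- rbind(-pref * dci, pref * (dci + dck), -pref * dck)
  rownames(g) <- c("i", "j", "k")
  list(energy = e, theta = acos(cth) * 180 / pi, grad = g)
}

#' Dipole orientation restraint
#'
#' Restrains a point dipole to lie along its reference bond vector through
#' `U = kd (1 - cos delta)`, `delta` being the angle between the dipole
#' axis and the bond.  The restoring torque on the dipole is
#' `kd (u x bhat)`; equal and opposite reaction forces act on the two
#' bond-defining sites so that total momentum and angular momentum are
#' conserved.
#'
#' @param u Unit dipole orientation vector.
#' @param ref_bond Reference bond vector (from the dipole-carrying site
#'   toward its bonded reference site), nm.
#' @param kd Rigidity, kJ/mol.
#' @return List with `energy`, `torque` (on the dipole, kJ/mol), `force_b`
#'   (force on the far bond site), `force_a` (= -`force_b`, on the
#'   dipole-carrying site).
#' @export
dipole_restraint <- function(u, ref_bond, kd) {
  lb <- sqrt(sum(ref_bond^2))
  if (lb == 0) stop("dipole_restraint: zero reference bond vector")
  bhat <- ref_bond / lb
  cd <- sum(u * bhat)
  e <- kd * (1 - cd)
  torque <- kd * .cross3(u, bhat)
  f_b <- kd * (u - cd * bhat) / lb
  list(energy = e, torque = torque, force_b = f_b, force_a = -f_b)
}
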