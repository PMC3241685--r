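# Independent oracles used to validate the compiled engine: an O(N^2)
# minimum-image energy/force sum built on the pure-R pair potentials, a
# finite-difference force/torque checker, and closed-form synthetic slab
# profiles for the analysis module.  None of this shares kernels with the
# C++ code paths it checks.

.min_image <- function(d, box) d - box * round(d / box)

#' Brute-force energy oracle
#'
#' Evaluates every ELBA energy term by an O(N^2) minimum-image double loop
#' over all site pairs (1-2 exclusions applied) plus explicit loops over
#' bonds, angles and restraints, using the pure-R pair potentials.  Used
#' to validate the cell-list engine; practical up to a few hundred sites.
#'
#' @inheritParams compute_forces
#' @return Named numeric vector of energy terms (kJ/mol): `lj`, `coulomb`,
#'   `charge_dipole`, `dipole_dipole`, `bond`, `angle`, `restraint`.
#' @export
brute_force_energy <- function(sys, ff) {
  n <- nrow(sys$pos)
  nm <- ff$sites$name
  q <- ff$sites$charge; mu <- ff$sites$dipole
  e <- c(lj = 0, coulomb = 0, charge_dipole = 0, dipole_dipole = 0,
         bond = 0, angle = 0, restraint = 0)
  excl <- matrix(FALSE, n, n)
  if (nrow(sys$bonds)) {
    excl[sys$bonds[, 1:2, drop = FALSE]] <- TRUE
    excl[sys$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (excl[i, j]) next
      ti <- sys$type[i]; tj <- sys$type[j]
      d <- .min_image(sys$pos[i, ] - sys$pos[j, ], sys$box)
      r <- sqrt(sum(d^2))
      mp <- mix_params(ff, nm[ti], nm[tj])
      if (r >= mp$cutoff) next
      e["lj"] <- e["lj"] +
        lj_shifted_force(r, mp$sigma_ij, mp$epsilon_ij, mp$cutoff)$energy
      if (q[ti] != 0 && q[tj] != 0)
        e["coulomb"] <- e["coulomb"] +
          coulomb_shifted_force(q[ti], q[tj], r, mp$cutoff)$energy
      if (q[ti] != 0 && mu[tj] > 0)
        e["charge_dipole"] <- e["charge_dipole"] +
          charge_dipole(q[ti], mu[tj] * sys$u[j, ], d, mp$cutoff)$energy
      if (q[tj] != 0 && mu[ti] > 0)
        e["charge_dipole"] <- e["charge_dipole"] +
          charge_dipole(q[tj], mu[ti] * sys$u[i, ], -d, mp$cutoff)$energy
      if (mu[ti] > 0 && mu[tj] > 0)
        e["dipole_dipole"] <- e["dipole_dipole"] +
          dipole_dipole(d, mu[ti] * sys$u[i, ], mu[tj] * sys$u[j, ],
                        mp$cutoff, mp$switch_radius)$energy
    }
  }
  if (nrow(sys$bonds))
    for (b in seq_len(nrow(sys$bonds))) {
      d <- .min_image(sys$pos[sys$bonds[b, 1], ] - sys$pos[sys$bonds[b, 2], ],
                      sys$box)
      e["bond"] <- e["bond"] +
        bond_energy(sqrt(sum(d^2)), sys$bonds[b, 3], sys$bonds[b, 4])$energy
    }
  if (nrow(sys$angles))
    for (a in seq_len(nrow(sys$angles))) {
      i <- sys$angles[a, 1]; j <- sys$angles[a, 2]; k <- sys$angles[a, 3]
      ri <- sys$pos[j, ] + .min_image(sys$pos[i, ] - sys$pos[j, ], sys$box)
      rk <- sys$pos[j, ] + .min_image(sys$pos[k, ] - sys$pos[j, ], sys$box)
      e["angle"] <- e["angle"] +
        angle_energy(ri, sys$pos[j, ], rk, sys$angles[a, 4],
                     sys$angles[a, 5], style = .angle_style(ff))$energy
    }
  if (nrow(sys$restraints))
    for (r_ in seq_len(nrow(sys$restraints))) {
      d <- sys$restraints[r_, 1]
      bvec <- .min_image(sys$pos[sys$restraints[r_, 3], ] -
                           sys$pos[sys$restraints[r_, 2], ], sys$box)
      e["restraint"] <- e["restraint"] +
        dipole_restraint(sys$u[d, ], bvec, sys$restraints[r_, 4])$energy
    }
  e
}

#' Finite-difference force and torque check
#'
#' Compares the engine's analytic forces against central differences of
#' the engine's total potential energy along every coordinate, and its
#' torques against energy derivatives under small rotations of each
#' dipole about two orthogonal axes.  Forces/torques below `floor`
#' (kJ/mol/nm or kJ/mol) are compared absolutely, the rest relatively.
#' The default step balances O(h^2) truncation (dominated by the steep
#' r^-12 repulsion wall) against round-off at double precision; the
#' truncation scaling can be confirmed by varying `h`.
#'
#' @inheritParams compute_forces
#' @param h Displacement step, nm (also used as rotation angle, rad).
#' @param tol Relative tolerance for the pass/fail verdict.
#' @param floor Magnitude below which absolute error is used.
#' @return List of class `oracle_report`: `max_force_err`,
#'   `max_torque_err` (relative), `pass`, `tol`, `h`.
#' @export
finite_difference_check <- function(sys, ff, h = 2e-6, tol = 1e-6,
                                    floor = 1e-4) {
  energy_of <- function(s) sum(compute_forces(s, ff)$energies)
  ref <- compute_forces(sys, ff)
  n <- nrow(sys$pos)
  scale_f <- max(abs(ref$forces), floor)
  max_fe <- 0
  for (i in seq_len(n)) for (a in 1:3) {
    sp <- sys; sp$pos[i, a] <- sp$pos[i, a] + h
    sm <- sys; sm$pos[i, a] <- sm$pos[i, a] - h
    fnum <- -(energy_of(sp) - energy_of(sm)) / (2 * h)
    denom <- max(abs(ref$forces[i, a]), floor * scale_f)
    max_fe <- max(max_fe, abs(fnum - ref$forces[i, a]) / denom)
  }
  max_te <- 0
  mu <- ff$sites$dipole[sys$type]
  for (i in which(mu > 0)) {
    u0 <- sys$u[i, ]
    e1 <- .perp_unit(u0); e2 <- .cross3(u0, e1)
    for (ax in list(e1, e2)) {
      rot <- function(ang) {
        s <- sys
        k <- ax
        s$u[i, ] <- u0 * cos(ang) + .cross3(k, u0) * sin(ang) +
          k * sum(k * u0) * (1 - cos(ang))
        s
      }
      tnum <- -(energy_of(rot(h)) - energy_of(rot(-h))) / (2 * h)
      tana <- sum(ref$torques[i, ] * ax)
      denom <- max(abs(tana), floor * max(abs(ref$torques), floor))
      max_te <- max(max_te, abs(tnum - tana) / denom)
    }
  }
  out <- list(max_force_err = max_fe, max_torque_err = max_te,
              pass = max_fe < tol && max_te < tol, tol = tol, h = h)
  class(out) <- "oracle_report"
  out
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf(
    "finite-difference check: %s (max force err %.3g, max torque err %.3g, tol %.1g)\n",
    if (x$pass) "PASS" else "FAIL", x$max_force_err, x$max_torque_err,
    x$tol))
  invisible(x)
}

#' Synthetic slab profiles with known closed forms
#'
#' Generates slab data whose analysis results are known analytically,
#' for validating the profile-analysis operations:
#' `"delta_peaks"` - a pressure profile with two symmetric delta-like
#' peaks of integrated weight `w` at `+/-z1` (first moment per monolayer
#' `w*z1`, second `w*z1^2`); `"constant"` - constant pressure `c0` over
#' each monolayer (first moment `c0*L^2/2`); `"capacitor"` - two opposite
#' uniform charge sheets of areal density `sigma_q` at `-d` and `+d`
#' (potential difference `sigma_q*2*d/eps0` between the plates);
#' `"dipole_layer"` - a uniform dipole sheet of areal density `P`
#' (potential step `P/eps0`).
#'
#' @param kind One of `"delta_peaks"`, `"constant"`, `"capacitor"`,
#'   `"dipole_layer"`.
#' @param Lz Box length along z, nm (profile spans `-Lz/2..Lz/2`).
#' @param nslab Number of slabs.
#' @param z1 Peak position (nm), `"delta_peaks"`.
#' @param w Integrated peak weight (atm nm), `"delta_peaks"`.
#' @param c0 Constant pressure (atm), `"constant"`.
#' @param sigma_q Sheet charge density (e/nm^2), `"capacitor"`.
#' @param d Sheet half-separation (nm), `"capacitor"`.
#' @param P Dipole areal density (e nm/nm^2 = e/nm), `"dipole_layer"`.
#' @return Data frame with `z` and, depending on kind, `pi` (atm) or
#'   `rho_q` (e/nm^3) and `P_z` (e/nm^2); the closed-form expectation is
#'   attached as attribute `expected`.
#' @export
synthetic_profile <- function(kind, Lz = 6, nslab = 60, z1 = 1, w = 100,
                              c0 = 50, sigma_q = 0.3, d = 1, P = 0.05) {
  kind <- match.arg(kind,
                    c("delta_peaks", "constant", "capacitor", "dipole_layer"))
  dz <- Lz / nslab
  z <- (seq_len(nslab) - 0.5) * dz - Lz / 2
  out <- data.frame(z = z)
  slab_at <- function(zp) which.min(abs(z - zp))
  if (kind == "delta_peaks") {
    p <- numeric(nslab)
    p[slab_at(z1)] <- w / dz
    p[slab_at(-z1)] <- w / dz
    out$pi <- p
    zu <- z[slab_at(z1)]; zl <- z[slab_at(-z1)]
    attr(out, "expected") <- list(M1 = w * (zu - zl) / 2,
                                  M2 = w * (zu^2 + zl^2) / 2)
  } else if (kind == "constant") {
    out$pi <- rep(c0, nslab)
    attr(out, "expected") <- list(M1 = c0 * (Lz / 2)^2 / 2,
                                  M2 = c0 * (Lz / 2)^3 / 3)
  } else if (kind == "capacitor") {
    rq <- numeric(nslab)
    rq[slab_at(-d)] <- sigma_q / dz
    rq[slab_at(d)] <- -sigma_q / dz
    out$rho_q <- rq
    out$P_z <- numeric(nslab)
    attr(out, "expected") <-
      list(delta_psi = sigma_q * 2 * abs(z[slab_at(d)]) * .INV_EPS0)
  } else {
    out$rho_q <- numeric(nslab)
    pz <- numeric(nslab)
    pz[slab_at(0)] <- P / dz
    out$P_z <- pz
    attr(out, "expected") <- list(psi_step = P * .INV_EPS0)
  }
  attr(out, "dz") <- dz
  out
}
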