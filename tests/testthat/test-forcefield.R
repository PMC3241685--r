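# Pair potentials, mixing rules and bonded terms, checked against frozen
# values from an independent symbolic evaluation and against central
# finite differences.

test_that("shifted-force Lennard-Jones vanishes smoothly at the cutoff", {
  out <- lj_shifted_force(0.9, 0.3, 1.95, 0.9)
  expect_identical(out$energy, 0)
  expect_identical(out$force, 0)
  h <- 1e-6
  near <- lj_shifted_force(0.9 - h, 0.3, 1.95, 0.9)
  expect_lt(abs(near$energy), 1e-8)
  expect_lt(abs(near$force), 1e-4)
  expect_identical(lj_shifted_force(1.5, 0.3, 1.95, 0.9)$energy, 0)
})

test_that("shifted-force Lennard-Jones matches the symbolic oracle", {
  # frozen values: sympy evaluation of the Stoddard-Ford expression with
  # the water parameters (sigma 0.3 nm, eps 1.95 kJ/mol, rc 0.9 nm)
  out <- lj_shifted_force(0.30, 0.3, 1.95, 0.9)
  expect_equal(out$energy, 0.03913886960170555, tolerance = 1e-12)
  expect_equal(out$force, 156.0237116318337, tolerance = 1e-12)
  out5 <- lj_shifted_force(0.50, 0.3, 1.95, 0.9)
  expect_equal(out5$energy, -0.3141221299998144, tolerance = 1e-12)
  expect_equal(out5$force, -3.9199885603113, tolerance = 1e-10)
})

test_that("radial forces match central differences of the energy", {
  h <- 1e-7
  for (r in c(0.3, 0.5, 0.8)) {
    fd <- -(lj_shifted_force(r + h, 0.3, 1.95, 0.9)$energy -
              lj_shifted_force(r - h, 0.3, 1.95, 0.9)$energy) / (2 * h)
    expect_equal(lj_shifted_force(r, 0.3, 1.95, 0.9)$force, fd,
                 tolerance = 1e-6)
    fdc <- -(coulomb_shifted_force(1, -1, r + h, 1.2)$energy -
               coulomb_shifted_force(1, -1, r - h, 1.2)$energy) / (2 * h)
    expect_equal(coulomb_shifted_force(1, -1, r, 1.2)$force, fdc,
                 tolerance = 1e-6)
    fdb <- -(bond_energy(r + h, 1260, 0.45)$energy -
               bond_energy(r - h, 1260, 0.45)$energy) / (2 * h)
    expect_equal(bond_energy(r, 1260, 0.45)$force, fdb, tolerance = 1e-6)
  }
})

test_that("domain errors are raised for non-physical separations", {
  expect_error(lj_shifted_force(0, 0.3, 1.95, 0.9), "r must be")
  expect_error(coulomb_shifted_force(1, 1, -0.1, 1.2), "r must be")
  expect_error(dipole_dipole(c(0, 0, 0), c(0, 0, 2.3), c(0, 0, 2.3), 0.9),
               "zero separation")
  expect_error(charge_dipole(1, c(0, 0, 2.3), c(0, 0, 0), 1.2),
               "zero separation")
  expect_error(dipole_restraint(c(0, 0, 1), c(0, 0, 0), 10),
               "zero reference")
})

test_that("dipole-dipole interaction reproduces closed-form geometries", {
  mu <- c(0, 0, 2.3)
  # collinear head-to-tail at r < switch radius: U = -2 ke mu^2 / r^3
  out <- dipole_dipole(c(0, 0, 0.5), mu, mu, 0.9, 0.81)
  expect_equal(out$energy, -5.097140312073522, tolerance = 1e-12)
  expect_equal(out$torque_i, c(0, 0, 0))
  # beyond cutoff: all outputs zero
  far <- dipole_dipole(c(0, 0, 1.0), mu, mu, 0.9, 0.81)
  expect_identical(far$energy, 0)
  expect_identical(far$force_i, c(0, 0, 0))
  # one dipole along rhat, the other orthogonal: energy 0
  perp <- dipole_dipole(c(0, 0, 0.5), mu, c(2.3, 0, 0), 0.9, 0.81)
  expect_equal(perp$energy, 0)
})

test_that("dipole-dipole force and torque agree with finite differences", {
  r0 <- c(0.2, 0.3, 0.75)            # inside the switching region
  mu_i <- 2.3 * c(0.6, -0.64, 0.48)
  mu_j <- 2.3 * c(-0.48, 0.6, 0.64)
  h <- 1e-7
  en <- function(rv) dipole_dipole(rv, mu_i, mu_j, 0.9, 0.81)$energy
  out <- dipole_dipole(r0, mu_i, mu_j, 0.9, 0.81)
  for (a in 1:3) {
    dp <- dm <- r0; dp[a] <- dp[a] + h; dm[a] <- dm[a] - h
    expect_equal(out$force_i[a], -(en(dp) - en(dm)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("shifted-force Coulomb matches the analytic oracle", {
  out <- coulomb_shifted_force(1, -1, 0.5, 1.2)
  expect_equal(out$energy, -94.55329780555553, tolerance = 1e-12)
  expect_equal(out$force, -459.25887505555556, tolerance = 1e-12)
  expect_identical(coulomb_shifted_force(1, -1, 1.2, 1.2)$energy, 0)
  expect_identical(coulomb_shifted_force(0, -1, 0.5, 1.2)$energy, 0)
})

test_that("charge-dipole interaction matches the analytic oracle", {
  # q = +1 e, mu = 2.3 D along rhat, r = 0.6 nm, rc = 1.2 nm
  out <- charge_dipole(1, c(0, 0, 2.3), c(0, 0, 0.6), 1.2)
  expect_equal(out$energy, 9.240114549456631, tolerance = 1e-12)
  # dipole perpendicular to rhat: zero energy
  expect_equal(charge_dipole(1, c(2.3, 0, 0), c(0, 0, 0.6), 1.2)$energy, 0)
  # beyond cutoff: all outputs zero
  far <- charge_dipole(1, c(0, 0, 2.3), c(0, 0, 1.3), 1.2)
  expect_identical(far$energy, 0)
  expect_identical(far$force_q, c(0, 0, 0))
  # energy and radial derivative vanish continuously at the cutoff
  h <- 1e-6
  near <- charge_dipole(1, c(0, 0, 2.3), c(0, 0, 1.2 - h), 1.2)
  expect_lt(abs(near$energy), 1e-8)
  expect_lt(max(abs(near$force_q)), 1e-4)
})

test_that("bond and angle terms follow the recorded conventions", {
  expect_equal(bond_energy(0.45, 1260, 0.45)$energy, 0)
  expect_equal(bond_energy(0.45, 1260, 0.45)$force, 0)
  expect_equal(bond_energy(0.50, 1260, 0.45)$energy, 1.575, tolerance = 1e-12)
  expect_equal(bond_energy(0.50, 1260, 0.45)$energy,
               bond_energy(0.40, 1260, 0.45)$energy)

  # theta = theta0: zero energy, zero gradient (both conventions)
  for (st in c("theta", "cosine")) {
    a0 <- angle_energy(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0), 30, 180, st)
    expect_equal(a0$energy, 0)
    expect_lt(max(abs(a0$grad)), 1e-6)
  }
  th <- 150 * pi / 180
  # cosine-harmonic frozen value at 150 degrees from 180
  ac <- angle_energy(c(1, 0, 0), c(0, 0, 0), c(cos(th), sin(th), 0), 30,
                     180, "cosine")
  expect_equal(ac$energy, 0.2692378864668403, tolerance = 1e-12)
  # harmonic value: (30/2) (30 deg in rad)^2
  a1 <- angle_energy(c(1, 0, 0), c(0, 0, 0), c(cos(th), sin(th), 0), 30, 180)
  expect_equal(a1$energy, 0.5 * 30 * (30 * pi / 180)^2, tolerance = 1e-12)
  # symmetric displacements about theta0 give equal energies
  a2 <- angle_energy(c(1, 0, 0), c(0, 0, 0), c(cos(th), -sin(th), 0), 30, 180)
  expect_equal(a1$energy, a2$energy)
  # gradient consistent with finite differences
  h <- 1e-7
  for (a in 1:3) {
    rp <- rm <- c(1, 0, 0); rp[a] <- rp[a] + h; rm[a] <- rm[a] - h
    fd <- -(angle_energy(rp, c(0, 0, 0), c(cos(th), sin(th), 0), 30, 180)$energy -
              angle_energy(rm, c(0, 0, 0), c(cos(th), sin(th), 0), 30, 180)$energy) / (2 * h)
    expect_equal(unname(a1$grad["i", a]), fd, tolerance = 1e-5)
  }
  expect_error(angle_energy(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), 30, 180),
               "degenerate")
})

test_that("dipole restraint restores alignment and conserves momenta", {
  b <- c(0, 0, 0.45)
  aligned <- dipole_restraint(c(0, 0, 1), b, 10)
  expect_equal(aligned$energy, 0)
  expect_equal(aligned$torque, c(0, 0, 0))
  # energy(delta) = energy(-delta)
  d <- 0.3
  e1 <- dipole_restraint(c(sin(d), 0, cos(d)), b, 10)$energy
  e2 <- dipole_restraint(c(-sin(d), 0, cos(d)), b, 10)$energy
  expect_equal(e1, e2)
  # delta = 90 degrees: U = kd
  out <- dipole_restraint(c(1, 0, 0), b, 10)
  expect_equal(out$energy, 10)
  # torque magnitude equals dE/ddelta = kd sin(delta) by finite difference
  h <- 1e-6
  ed <- function(dd) dipole_restraint(c(sin(dd), 0, cos(dd)), b, 10)$energy
  expect_equal(sqrt(sum(out$torque^2)), (ed(pi / 2 + h) - ed(pi / 2 - h)) / (2 * h),
               tolerance = 1e-6)
  # reaction forces: total force and torque about the origin vanish
  u <- c(sin(d), 0, cos(d))
  r <- dipole_restraint(u, b, 10)
  expect_equal(r$force_a + r$force_b, c(0, 0, 0))
  tot <- r$torque + elbamd:::.cross3(b, r$force_b)
  expect_equal(max(abs(tot)), 0, tolerance = 1e-12)
})

test_that("Lorentz-Berthelot mixing with hydrogen-bond scalings", {
  expect_equal(mix_params(ff_test, "choline", "water")$sigma_ij, 0.41)
  expect_equal(mix_params(ff_test, "tail", "water")$epsilon_ij,
               1.396424004376894, tolerance = 1e-12)
  # symmetry
  m1 <- mix_params(ff_test, "water", "phosphate")
  m2 <- mix_params(ff_test, "phosphate", "water")
  expect_identical(m1, m2)
  # hydrogen-bond pairs are scaled, all other pairs are not
  expect_gt(m1$s_ij, 1)
  expect_identical(mix_params(ff_test, "choline", "tail")$s_ij, 1)
  expect_identical(mix_params(ff_test, "tail", "tail")$s_ij, 1)
  hb_pairs <- list(c("water", "phosphate"), c("water", "glycerol"),
                   c("water", "ester"), c("amine", "phosphate"),
                   c("amine", "glycerol"), c("amine", "ester"),
                   c("amine", "water"))
  for (p in hb_pairs)
    expect_gt(mix_params(ff_test, p[1], p[2])$s_ij, 1)
  # water-water pairs use the short cutoff, everything else the long one
  expect_equal(mix_params(ff_test, "water", "water")$cutoff, 0.9)
  expect_equal(mix_params(ff_test, "water", "tail")$cutoff, 1.2)
  expect_error(mix_params(ff_test, "cholesterol", "water"), "unknown")
})

test_that("reference bond lengths follow the sigma combination rule", {
  sig_t <- ff_test$sites$sigma[match("tail", ff_test$sites$name)]
  expect_equal(reference_bond_length(ff_test, "tail", "tail"), sig_t)
  r_gp <- reference_bond_length(ff_test, "glycerol", "phosphate")
  expect_equal(r_gp, (0.45 + 0.46) / 2)
  expect_equal(r_gp, reference_bond_length(ff_test, "phosphate", "glycerol"))
  # monotone in either sigma
  nm <- ff_test$sites$name
  base <- reference_bond_length(ff_test, "water", "water")
  for (t in nm)
    expect_gte(reference_bond_length(ff_test, t, "water"), base)
})
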