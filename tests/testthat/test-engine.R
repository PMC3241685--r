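# Engine correctness: neighbour search, force accumulation against the
# pure-R oracle, Newton's third law, integrator contracts, couplings.

test_that("neighbour list matches an exhaustive pair scan", {
  sys <- random_mixed_system(n_lipids = 2, n_water = 150, seed = 31)
  skin <- 0.2
  nl <- neighbor_list(sys, ff_test, skin)
  key <- paste(nl[, 1], nl[, 2])
  n <- nrow(sys$pos)
  nm <- ff_test$sites$name
  bonded <- matrix(FALSE, n, n)
  bonded[sys$bonds[, 1:2]] <- TRUE
  bonded <- bonded | t(bonded)
  expected <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sys$pos[i, ] - sys$pos[j, ]
    d <- d - round(d / sys$box) * sys$box
    rc <- mix_params(ff_test, nm[sys$type[i]], nm[sys$type[j]])$cutoff
    if (sum(d^2) < (rc + skin)^2 && !bonded[i, j])
      expected <- c(expected, paste(i, j))
  }
  expect_setequal(key, expected)
  # directly bonded pairs never appear
  bkey <- paste(pmin(sys$bonds[, 1], sys$bonds[, 2]),
                pmax(sys$bonds[, 1], sys$bonds[, 2]))
  expect_length(intersect(key, bkey), 0)
})

test_that("engine energies equal the brute-force oracle", {
  for (seed in c(31, 77)) {
    sys <- random_mixed_system(n_lipids = 2, n_water = 150, seed = seed)
    eng <- compute_forces(sys, ff_test)$energies
    ora <- brute_force_energy(sys, ff_test)
    expect_equal(unname(eng), unname(ora), tolerance = 1e-10)
  }
})

test_that("pair forces obey Newton's third law", {
  sys <- random_mixed_system(seed = 55)
  f <- compute_forces(sys, ff_test)$forces
  expect_lt(max(abs(colSums(f))), 1e-9 * mean(abs(f)))
})

test_that("analytic forces and torques pass the finite-difference oracle", {
  # dipolar water cluster
  sysw <- build_water_box(64, density = 0.25, temperature = 300,
                          ff = ff_test, seed = 3)
  expect_true(finite_difference_check(sysw, ff_test)$pass)
  # a full lipid in vacuum exercises bonds, angles, restraints and the
  # intramolecular 1-3+ nonbonded terms
  sysl <- build_random_dispersion("DOPC", 1, hydration = 4,
                                  total_density = 0.05, ff = ff_test,
                                  seed = 8)
  # relax away the compacted-placement overlaps so finite differences
  # probe a physical configuration
  sysl <- relax_ramp(sysl, ff_test, 303, steps = 1200,
                     leaflet_remove = FALSE)
  rep_l <- finite_difference_check(sysl, ff_test, tol = 1e-5)
  expect_true(rep_l$pass)
})

test_that("free motion: straight lines and uniform dipole rotation", {
  # two waters far apart in a large box: no interactions
  pos <- rbind(c(1, 1, 1), c(4, 4, 4))
  sys <- toy_system(pos, c("water", "water"), box = c(6, 6, 6))
  sys$vel <- rbind(c(0.1, 0, 0), c(0, -0.05, 0.02))
  sys$u <- rbind(c(0, 0, 1), c(1, 0, 0))
  sys$omega <- rbind(c(0, 2, 0), c(0, 0, 1))
  r <- run_md(sys, ff_test, 100, sim_config("nve", dt = 0.01, e_stride = 0))
  t_tot <- 1.0
  expect_equal(r$system$pos[1, ], pos[1, ] + c(0.1, 0, 0) * t_tot,
               tolerance = 1e-12)
  # orientation precesses about omega by |omega| * t
  ang <- 2 * t_tot
  expect_equal(r$system$u[1, ], c(sin(ang), 0, cos(ang)), tolerance = 1e-9)
  expect_equal(sqrt(sum(r$system$u[2, ]^2)), 1, tolerance = 1e-12)
})

test_that("dipole norms are preserved over long runs", {
  sys <- build_water_box(64, density = 0.3, temperature = 303,
                         ff = ff_test, seed = 17)
  r <- run_md(sys, ff_test, 10000, sim_config("nve", dt = 0.01, e_stride = 0))
  expect_lt(max(abs(sqrt(rowSums(r$system$u^2)) - 1)), 1e-10)
})

test_that("harmonic dimer oscillates at the analytic period", {
  # two tail sites bonded with kb = 1260, displaced from r0
  r0 <- 0.45
  pos <- rbind(c(2, 2, 2), c(2, 2, 2 + r0 + 0.05))
  bonds <- matrix(c(1, 2, 1260, r0), 1, 4)
  sys <- toy_system(pos, c("tail", "tail"), box = c(4, 4, 4), bonds = bonds,
                    species = rep("DOPC", 2), mol = c(1, 1))
  dt <- 0.001
  r <- run_md(sys, ff_test, 4096, sim_config("nve", dt = dt, e_stride = 1))
  # the kinetic energy oscillates at twice the bond frequency; read the
  # dominant spectral line
  ke <- r$elog$KE_trans
  sp <- Mod(stats::fft(ke - mean(ke)))[2:(length(ke) %/% 2)]
  k <- which.max(sp) + 1
  t_ke <- length(ke) * dt / (k - 1)
  t_bond <- 2 * t_ke
  m_red <- 42 / 2
  t_analytic <- 2 * pi * sqrt(m_red / 1260)
  expect_equal(t_bond, t_analytic, tolerance = 0.02)
})

test_that("weak-coupling thermostat factors behave as specified", {
  expect_equal(berendsen_lambda(300, 300, 0.015, 1), 1)
  ts <- seq(250, 400, by = 10)
  lam <- berendsen_lambda(ts, 300, 0.015, 1)
  expect_true(all(diff(lam) < 0))      # monotone decreasing in T_inst
  sys <- build_water_box(64, density = 0.5, temperature = 310,
                         ff = ff_test, seed = 21)
  sys2 <- weak_coupling_thermostat(sys, ff_test, T0 = 310)
  # groups start exactly at target translational T: rescaling is tiny
  expect_equal(sys2$vel, sys$vel, tolerance = 1e-2)
})

test_that("long-run kinetic temperature tracks the thermostat target", {
  sys <- build_water_box(216, temperature = 303, ff = ff_test, seed = 23)
  r <- run_md(sys, ff_test, 6000,
              sim_config("nvt", temperature = 303, e_stride = 20))
  tmean <- mean(tail(r$elog$T, 200))
  expect_lt(abs(tmean - 303) / 303, 0.01)
})

test_that("weak-coupling barostat respects its mode contracts", {
  expect_equal(berendsen_mu(1, 1, 0.015, 5), 1)
  sys <- build_water_box(216, temperature = 303, ff = ff_test, seed = 29)
  sys2 <- weak_coupling_barostat(sys, ff_test, "semi-isotropic")
  expect_equal(sys2$box[1], sys2$box[2])
  # semi-isotropic runs keep the interface square exactly
  r <- run_md(sys, ff_test, 500,
              sim_config("npt-semi", temperature = 303, e_stride = 10))
  expect_equal(r$elog$Lx, r$elog$Ly, tolerance = 1e-12)
})

test_that("drift removal zeroes momenta as specified", {
  sys <- build_bilayer("DOPC", 8, hydration = 12, ff = ff_test, seed = 3)
  sys$vel <- sys$vel + matrix(c(0.05, -0.02, 0.01),
                              nrow(sys$vel), 3, byrow = TRUE)
  out <- remove_drift(sys, ff_test)
  m <- ff_test$sites$mass[out$type]
  expect_lt(max(abs(colSums(out$vel * m))), 1e-10)
  for (lf in 0:1) {
    sel <- out$group == 1 & !is.na(out$leaflet) & out$leaflet == lf
    expect_lt(max(abs(colSums(out$vel[sel, 1:2] * m[sel]))), 1e-10)
  }
  # normal components of lipid velocities untouched by leaflet removal
  just_com <- sweep(sys$vel, 2, colSums(sys$vel * m) / sum(m))
  sel <- out$group == 1
  expect_equal(out$vel[sel, 3], just_com[sel, 3], tolerance = 1e-12)
})

test_that("runs are deterministic and observers honour their strides", {
  sys <- build_water_box(64, density = 0.25, temperature = 303,
                         ff = ff_test, seed = 41)
  cfg <- sim_config("nvt", temperature = 303, e_stride = 7, x_stride = 13)
  r1 <- run_md(sys, ff_test, 100, cfg)
  r2 <- run_md(sys, ff_test, 100, cfg)
  expect_identical(r1$elog, r2$elog)
  expect_equal(nrow(r1$elog), 100 %/% 7)
  expect_equal(dim(r1$traj$pos)[3], 100 %/% 13)
  expect_equal(r1$elog$step, seq(7, 98, by = 7))
})

test_that("degenerate configurations raise errors", {
  pos <- rbind(c(1, 1, 1), c(1, 1, 1 + 1e-8))
  sys <- toy_system(pos, c("water", "water"), box = c(6, 6, 6))
  expect_error(compute_forces(sys, ff_test), "overlapping")
  sys2 <- build_water_box(27, density = 2.5, temperature = 300,
                          ff = ff_test, seed = 2)
  expect_error(compute_forces(sys2, ff_test), "box length")
})

test_that("NVE runs conserve energy and momentum", {
  sys <- cached("water216_nvt", {
    s <- build_water_box(216, temperature = 303, ff = ff_test, seed = 2)
    run_md(s, ff_test, 3000, sim_config("nvt", temperature = 303,
                                        e_stride = 0))$system
  })
  r <- run_md(sys, ff_test, 3000, sim_config("nve", e_stride = 50))
  E <- r$elog$E_total
  drift <- abs(mean(tail(E, 6)) - mean(head(E, 6))) / abs(mean(E))
  expect_lt(drift, 1e-3)
  m <- ff_test$sites$mass[r$system$type]
  expect_lt(max(abs(colSums(r$system$vel * m))), 1e-8)
})
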