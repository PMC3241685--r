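# Analysis observables against closed forms.

test_that("order parameter hits its closed-form limits", {
  sys <- build_bilayer("DSPC", 8, hydration = 0, ff = ff_test, seed = 1)
  idx_by_mol <- split(seq_along(sys$mol), sys$mol)
  set_tails <- function(sys, dirfun) {
    for (idx in idx_by_mol) {
      nm <- sys$site_name[idx]
      for (ch in c("a", "b")) {
        sites <- idx[match(paste0("tail_", ch, 1:5), nm)]
        base <- sys$pos[sites[1], ]
        dir <- dirfun()
        for (k in 2:5)
          sys$pos[sites[k], ] <- base + (k - 1) * 0.4 * dir
      }
    }
    sys
  }
  along_z <- set_tails(sys, function() c(0, 0, 1))
  expect_equal(order_parameter(as_trajectory(along_z))$global, 1)
  in_plane <- set_tails(sys, function() c(1, 0, 0))
  expect_equal(order_parameter(as_trajectory(in_plane))$global, -0.5)
  # isotropic random bonds: S -> 0 as samples grow
  set.seed(99)
  s_iso <- mean(replicate(80, {
    iso <- set_tails(sys, function() {
      v <- stats::rnorm(3); v / sqrt(sum(v^2))
    })
    order_parameter(as_trajectory(iso))$global
  }))
  expect_lt(abs(s_iso), 0.05)
})

test_that("electron density conserves totals and localises single sites", {
  set.seed(7)
  n_w <- 400
  sys <- toy_system(matrix(runif(n_w * 3, 0, 3.2), n_w, 3),
                    rep("water", n_w), box = c(3.2, 3.2, 3.2))
  sys$electrons <- rep(10, n_w)
  traj <- as_trajectory(sys)
  ed <- electron_density_profile(traj, ff_test)
  A <- sys$box[1] * sys$box[2]
  dz <- sys$box[3] / attr(ed, "nslab")
  expect_equal(sum(ed$density) * A * dz, n_w * 10, tolerance = 1e-10)
  # uniform box: profile flat at N * 10 / V within counting noise
  expect_lt(stats::sd(ed$density) / mean(ed$density), 0.35)
  expect_equal(mean(ed$density), n_w * 10 / prod(sys$box), tolerance = 1e-10)
  # single site: delta-like slab of height electrons / (A dz)
  one <- toy_system(matrix(c(1, 1, 2.0), 1, 3), "water", box = c(4, 4, 4))
  one$electrons <- 10
  ed1 <- electron_density_profile(as_trajectory(one), ff_test)
  expect_equal(max(ed1$density), 10 / (16 * 4 / attr(ed1, "nslab")),
               tolerance = 1e-10)
  expect_equal(sum(ed1$density > 0), 1)
})

test_that("electrostatic potential reproduces capacitor and dipole-layer closed forms", {
  # capacitor: square sheets of +/- charge at -d and +d (choline and
  # phosphate sites carry +/-0.7 e)
  nside <- 6; L <- 3; d <- 0.75
  g <- as.matrix(expand.grid(x = (1:nside - 0.5) * L / nside,
                             y = (1:nside - 0.5) * L / nside))
  Lz <- 6
  pos <- rbind(cbind(g, Lz / 2 - d), cbind(g, Lz / 2 + d))
  types <- rep(c("choline", "phosphate"), each = nside^2)
  sys <- toy_system(pos, types, box = c(L, L, Lz))
  psi <- electrostatic_potential_profile(as_trajectory(sys), ff_test)
  sigma_q <- 0.7 * nside^2 / L^2
  expected <- sigma_q * 2 * d * elba_constants()$inv_eps0
  # field vanishes outside a neutral capacitor; the potential difference
  # between the two outside regions is sigma_q * 2d / eps0 (positive on
  # the positive-plate side)
  step <- mean(psi$psi[psi$z < -(d + 0.2)]) -
    mean(psi$psi[psi$z > d + 0.2])
  expect_equal(step, expected, tolerance = 1e-3)

  # dipole layer: waters in a plane, all pointing +z
  wpos <- cbind(g, Lz / 2)
  wsys <- toy_system(wpos, rep("water", nside^2), box = c(L, L, Lz))
  wsys$u <- matrix(rep(c(0, 0, 1), each = nside^2), ncol = 3)
  wpsi <- electrostatic_potential_profile(as_trajectory(wsys), ff_test)
  P_areal <- 2.3 * elba_constants()$debye * nside^2 / L^2
  expected_step <- P_areal * elba_constants()$inv_eps0
  above <- wpsi$z > 0.5; below <- wpsi$z < -0.5
  expect_equal(mean(wpsi$psi[above]) - mean(wpsi$psi[below]), expected_step,
               tolerance = 1e-6)

  # no charges, no dipoles: psi identically zero
  tsys <- toy_system(wpos, rep("tail", nside^2), box = c(L, L, Lz),
                     species = rep("DOPC", nside^2))
  tpsi <- electrostatic_potential_profile(as_trajectory(tsys), ff_test)
  expect_equal(max(abs(tpsi$psi)), 0)
})

test_that("curvature moments reproduce synthetic-profile closed forms", {
  atm <- elba_constants()$atm_per_kjmolnm3
  # two symmetric delta peaks: M1 = w z1, M2 = w z1^2 per monolayer
  sp <- synthetic_profile("delta_peaks", Lz = 6, nslab = 120, z1 = 1.2,
                          w = 80)
  ce <- curvature_elastics(sp, kc_bilayer = 40)
  exp_ <- attr(sp, "expected")
  expect_equal(ce$M1, exp_$M1 / atm, tolerance = 1e-10)
  expect_equal(ce$M2, exp_$M2 / atm, tolerance = 1e-10)
  expect_equal(ce$c0, -ce$M1 / 20)
  # delta peaks are the global minima-free case; pivotal distance from
  # the peak positions here equals z1 (peaks are also the extrema)
  # constant profile: M1 = c L^2 / 2, M2 = c L^3 / 3
  cp <- synthetic_profile("constant", Lz = 6, nslab = 120, c0 = 50)
  cce <- curvature_elastics(cp)
  expc <- attr(cp, "expected")
  expect_equal(cce$M1, expc$M1 / atm, tolerance = 1e-4)
  expect_equal(cce$M2, expc$M2 / atm, tolerance = 1e-3)
  # zero profile: all moments and the spontaneous curvature vanish
  zp <- synthetic_profile("constant", c0 = 0)
  zce <- curvature_elastics(zp, kc_bilayer = 40)
  expect_equal(zce$M1, 0)
  expect_equal(zce$M2, 0)
  expect_equal(zce$c0, 0)
  expect_equal(zce$kappa_G, 0)
  # monolayer modulus is half the bilayer modulus
  expect_equal(zce$kappa_m, 20)
})

test_that("diffusion estimators recover closed-form motion", {
  # frozen trajectory: D = 0
  xy <- array(rep(runif(2 * 10), 30), dim = c(2, 10, 30))
  traj <- synthetic_com_traj(xy)
  expect_equal(lateral_diffusion(traj, ff_test)$D_nm2_ps, 0)
  # ballistic motion at speed v: MSD(t) = v^2 t^2
  v <- 0.07; nf <- 40
  xyb <- array(0, dim = c(2, 5, nf))
  for (f in seq_len(nf)) xyb[1, , f] <- v * (f - 1)
  mb <- msd_curve(synthetic_com_traj(xyb), ff_test, species = "DOPC",
                  lateral = TRUE)
  expect_equal(mb$msd, (v * mb$t)^2, tolerance = 1e-10)
  # 2-D random walk of known step variance: D = var / (2 dt) per axis
  set.seed(4)
  nmol <- 60; nf <- 400; step_sd <- 0.05
  steps <- array(rnorm(2 * nmol * (nf - 1), 0, step_sd),
                 dim = c(2, nmol, nf - 1))
  xyr <- array(0, dim = c(2, nmol, nf))
  for (f in 2:nf) xyr[, , f] <- xyr[, , f - 1] + steps[, , f - 1]
  D_true <- step_sd^2 / 2            # nm^2/ps with dt = 1 ps
  dl <- lateral_diffusion(synthetic_com_traj(xyr), ff_test,
                          t_meas = 100, n_origins = 26)
  expect_equal(dl$D_nm2_ps, D_true, tolerance = 0.05)
})

test_that("area compressibility matches the fluctuation closed form", {
  set.seed(11)
  n <- 4000
  A0 <- 10; sdA <- 0.08
  Lx <- sqrt(A0 + rnorm(n, 0, sdA))
  elog <- data.frame(Lx = Lx, Ly = Lx, Lz = 8, T = 303)
  fake_run <- structure(list(system = list(mol = rep(1:8, each = 15),
                                           group = rep(1L, 120)),
                             elog = elog, traj = NULL),
                        class = "elba_run")
  fake_run$system$group <- rep(1L, 120)
  ss <- structural_summary(fake_run, ff_test)
  A <- elog$Lx * elog$Ly
  K_expect <- elba_constants()$kB * 303 * mean(A) / stats::var(A) *
    elba_constants()$dyncm_per_kjmolnm2
  expect_equal(ss$K_A, K_expect, tolerance = 1e-10)
  expect_equal(ss$area_per_lipid, 2 * mean(A) / 8 * 100, tolerance = 1e-10)
  # degenerate case: zero variance flags a non-finite modulus
  elog0 <- data.frame(Lx = rep(sqrt(A0), 50), Ly = rep(sqrt(A0), 50),
                      Lz = 8, T = 303)
  fr0 <- fake_run; fr0$elog <- elog0
  expect_warning(ss0 <- structural_summary(fr0, ff_test), "variance")
  expect_false(is.finite(ss0$K_A))
})

test_that("permeability counting follows the hysteresis rule and Fick form", {
  # N_cross = 10, t = 100 ns, A = 40 nm^2, dc = 33.4 nm^-3:
  # P = (10/2)/(1e5 ps * 40 nm^2 * 33.4 nm^-3) = 3.7425e-8 nm/ps
  P_direct <- (10 / 2) / (1e5 * 40 * 33.4)
  expect_equal(P_direct, 3.74251497005988e-08, tolerance = 1e-12)
  # doubling t with the same count halves P
  expect_equal((10 / 2) / (2e5 * 40 * 33.4), P_direct / 2)
  # build a synthetic water trajectory around a fake membrane at |z|<1:
  # one molecule crosses fully, one only recrosses the interface
  nf <- 9
  zs <- rbind(
    c(3, 2.5, 1.5, 0.5, -0.5, -1.5, -2.5, -3, -3),   # full crossing
    c(3, 2.0, 1.2, 0.8, 1.2, 0.8, 1.4, 2.5, 3))      # interfacial return
  n <- nrow(zs)
  Lz <- 8
  pos <- array(0, dim = c(3, n, nf))
  for (f in seq_len(nf)) pos[3, , f] <- zs[, f] + Lz / 2
  traj <- list(pos = pos, u = array(0, dim = c(3, n, nf)),
               box = matrix(c(5, 8, Lz), nf, 3, byrow = TRUE),
               time = (seq_len(nf) - 1) * 10,
               type = rep(match("water", ff_test$sites$name), n),
               mol = seq_len(n), species = rep("water", n),
               site_name = rep("water", n), electrons = rep(10, n),
               leaflet = rep(NA_integer_, n), group = rep(0L, n),
               ff_checksum = ff_test$checksum)
  class(traj) <- "elba_trajectory"
  out <- water_permeability(traj, ff_test, bounds = c(-1, 1), dc = 33.4)
  expect_equal(out$n_cross, 1)
  expect_equal(out$P_nm_ps, (1 / 2) / (80 * 40 * 33.4), tolerance = 1e-12)
  # zero crossings give zero permeability; doubling t halves P
  expect_equal(water_permeability(traj, ff_test,
                                  bounds = c(-5, 5))$n_cross * 1, 0)
})

test_that("slab pressure accumulators close against the global tensor", {
  sys <- build_water_box(216, temperature = 303, ff = ff_test, seed = 55)
  sys <- run_md(sys, ff_test, 1500,
                sim_config("nvt", temperature = 303, e_stride = 0))$system
  # exact bookkeeping identity on a single step: the slab-average normal
  # and tangential pressures equal the global tensor components
  r1 <- run_md(sys, ff_test, 1, sim_config("nvt", temperature = 303,
                                           e_stride = 1, prof_stride = 1))
  pp1 <- lateral_pressure_profile(r1)
  expect_equal(mean(pp1$P_N), r1$elog$Pzz, tolerance = 1e-10)
  expect_equal(mean(pp1$P_T), (r1$elog$Pxx + r1$elog$Pyy) / 2,
               tolerance = 1e-10)
  # homogeneous fluid: pi(z) fluctuates about zero with no structure
  r <- run_md(sys, ff_test, 4000,
              sim_config("nvt", temperature = 303, e_stride = 20,
                         prof_stride = 5))
  pp <- lateral_pressure_profile(r)
  expect_lt(abs(mean(pp$pi)), 200)            # atm; liquid-state noise scale
  expect_lt(abs(mean(pp$P_N) - mean(r$elog$Pzz)), 200)
})

test_that("structural summary of a small bilayer run is physically sane", {
  sys <- build_bilayer("DOPC", 18, hydration = 10, temperature = 303,
                       ff = ff_test, seed = 77)
  sys <- relax_ramp(sys, ff_test, 303, steps = 1600)
  r <- run_md(sys, ff_test, 2500,
              sim_config("npt-semi", temperature = 303,
                         leaflet_remove = TRUE, e_stride = 20,
                         x_stride = 250))
  expect_equal(r$status, "ok")
  ss <- structural_summary(r, ff_test)
  expect_equal(ss$n_lipids, 18)
  expect_gt(ss$area_per_lipid, 40)
  expect_lt(ss$area_per_lipid, 110)
  expect_true(is.finite(ss$K_A) && ss$K_A > 0)
  expect_gt(ss$head_dipole, 0)
  expect_true(ss$head_tilt >= 0 && ss$head_tilt <= 90)
  expect_gt(ss$thickness, 2)
  expect_lt(ss$thickness, 8)
})
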