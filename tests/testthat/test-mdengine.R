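test_that("radius of gyration matches closed forms and the double-loop formula", {
  x1 <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  expect_equal(compute_rg(x1, 1:4), 0)
  x2 <- rbind(c(0, 0, 0), c(0, 0, 0.8))
  expect_equal(compute_rg(x2, 1:2), 0.4) # two points distance d: Rg = d/2
  set.seed(11)
  x <- matrix(rnorm(96), 32, 3)
  cm <- colMeans(x)
  brute <- sqrt(mean(rowSums(sweep(x, 2, cm)^2)))
  expect_equal(compute_rg(x, 1:32), brute, tolerance = 1e-12)
  expect_error(compute_rg(x, 1L), "2 selected")
})

test_that("broken-molecule guard fires when a bond spans more than half the box", {
  x <- rbind(c(0.1, 0.1, 0.1), c(1.9, 0.1, 0.1))
  bonds <- cbind(1, 2, 0.4, 1000)
  expect_error(compute_rg(x, 1:2, box = rep(2.5, 3), bonds = bonds),
               "broken molecule")
  expect_silent(compute_rg(x, 1:2, box = rep(4, 3), bonds = bonds))
})

test_that("Rg restraint energy and forces behave like the harmonic bias", {
  set.seed(5)
  x <- matrix(rnorm(30, sd = 0.4), 10, 3)
  sel <- 1:10
  rg <- compute_rg(x, sel)
  # zero energy and force at the target
  at <- rg_restraint_energy_forces(x, rg_restraint(rg, 20000, sel))
  expect_equal(at$energy, 0, tolerance = 1e-9)
  expect_equal(max(abs(at$forces)), 0, tolerance = 1e-6)
  # energy value and finite-difference forces off target
  res <- rg_restraint(0.7, 20000, sel)
  out <- rg_restraint_energy_forces(x, res)
  expect_equal(out$energy, 0.5 * 20000 * (rg - 0.7)^2)
  fd <- num_grad(function(xx)
    rg_restraint_energy_forces(xx, res)$energy, x)
  expect_equal(out$forces, -fd, tolerance = 1e-5)
  # net force zero, translation invariance
  expect_equal(colSums(out$forces), c(0, 0, 0), tolerance = 1e-9)
  shifted <- rg_restraint_energy_forces(sweep(x, 2, c(3, -1, 2), "+"), res)
  expect_equal(shifted$energy, out$energy)
  expect_equal(shifted$forces, out$forces, tolerance = 1e-9)
})

test_that("pair energy reduces to the single-pair kernel and obeys Newton's third law", {
  sp <- species("Ar", 0.34, 1.0, 40, "water")
  ff <- build_forcefield(sp, cutoff = 1.2)
  x <- rbind(c(1, 1, 1), c(1, 1, 1.45))
  sys <- md_system(x, 6, c(1L, 1L), sp)
  out <- total_energy_forces(sys, ff)
  expect_equal(unname(out$energy[["pair"]]),
               ref_lj(0.45, 0.34, 1.0, 1.2))
  expect_equal(colSums(out$forces), c(0, 0, 0), tolerance = 1e-10)
})

test_that("cell-list evaluation equals the all-pairs double loop", {
  fl <- tiny_fluid(n = 50, box = 3.8, sigma = 0.34)
  fl$ff$cutoff <- 1.1
  brute <- total_energy_forces(fl$sys, fl$ff, neighbor_mode = 0L)
  cells <- total_energy_forces(fl$sys, fl$ff, neighbor_mode = 1L)
  expect_equal(brute$energy, cells$energy, tolerance = 1e-12)
  expect_equal(brute$forces, cells$forces, tolerance = 1e-10)
  # and against the plain-R reference
  expect_equal(unname(brute$energy[["pair"]]),
               ref_pair_energy(fl$sys$x, fl$sys$box, 0.34, 1.0, 1.1),
               tolerance = 1e-9)
})

test_that("every force term matches finite differences on random configurations", {
  spec <- reduced_solvent_spec("ethanol")
  set.seed(9)
  for (k in 1:4) {
    sys <- build_mixture(spec, 0.4, 12, seed = k, box = 2.0,
                         polymer = make_conformers(5, "coil", seed = k,
                                                   target_rg = 0.35))
    ff <- mixture_forcefield(spec)
    ff <- set_pair_mode(ff, "polymer", "water", "softcore")
    ff <- set_lambda(ff, 0.55)
    sel <- polymer_selection(sys)
    restr <- list(rg_restraint(0.5, 5000, sel),
                  position_restraint(sys$x[sel[1:2], ] + 0.01, 2000, sel[1:2]))
    out <- total_energy_forces(sys, ff, restr)
    fd <- num_grad(function(xx) {
      s2 <- sys; s2$x <- xx
      sum(total_energy_forces(s2, ff, restr)$energy[["total"]])
    }, sys$x, h = 2e-7)
    expect_equal(unname(out$forces), unname(-fd), tolerance = 5e-5)
  }
})

test_that("frictionless zero-temperature limit conserves energy (velocity Verlet)", {
  sp <- species("Ar", 0.34, 1.0, 40, "water")
  ff <- build_forcefield(sp, cutoff = 1.2)
  x <- rbind(c(2, 2, 2), c(2, 2, 2.45))
  sys <- md_system(x, 6, c(1L, 1L), sp)
  sys$v <- rbind(c(0, 0, 0.05), c(0, 0, -0.05))
  spec <- integrator_spec(dt = 0.002, temperature = 0, friction_time = 1e12)
  out <- run_segment(sys, ff, spec, 500, seed = 1, stride = 1)
  etot <- out$records$e_pair + out$records$e_kin
  drift <- max(abs(etot - etot[1]))
  expect_lt(drift / 500, 1e-5) # kJ/mol per step
})

test_that("same seed gives identical trajectories; advancing zero steps is a no-op", {
  fl <- tiny_fluid(n = 30, box = 2.2)
  sys <- maxwell_velocities(fl$sys, 300, 8)
  a <- run_segment(sys, fl$ff, integrator_spec(), 200, seed = 99, stride = 10)
  b <- run_segment(sys, fl$ff, integrator_spec(), 200, seed = 99, stride = 10)
  expect_identical(a$system$x, b$system$x)
  expect_identical(a$records, b$records)
  c2 <- run_segment(sys, fl$ff, integrator_spec(), 200, seed = 100, stride = 10)
  expect_false(identical(a$system$x, c2$system$x))
  z <- run_segment(sys, fl$ff, integrator_spec(), 0, seed = 1, stride = 10)
  expect_equal(unname(z$system$x), unname(sys$x))
  expect_equal(nrow(z$records), 0)
  # observer count contract
  expect_equal(nrow(run_segment(sys, fl$ff, integrator_spec(), 100,
                                seed = 1, stride = 10)$records), 10)
})

test_that("Rg under the umbrella bias fluctuates around the target with var ~ RT/k", {
  poly <- make_conformers(16, "coil", seed = 2, target_rg = 0.55)
  ff <- build_forcefield(poly$species)
  res <- rg_restraint(0.55, 20000, 1:16)
  sys <- maxwell_velocities(poly, 300, 3)
  out <- run_segment(sys, ff, integrator_spec(), 6000, list(res), seed = 4,
                     stride = 5)
  rgs <- out$records$rg[-(1:200)]
  expect_lt(abs(mean(rgs) - 0.55), 0.03)
  # harmonic fluctuation: var <= RT/k_b (bonded terms only stiffen)
  expect_lt(var(rgs), 3 * RT300 / 20000)
  expect_gt(var(rgs), RT300 / 20000 / 10)
})

test_that("steepest descent lowers the energy and relaxes overlaps", {
  sp <- species("Ar", 0.34, 1.0, 40, "water")
  ff <- build_forcefield(sp, cutoff = 1.2)
  # already-minimal dimer stays put
  dim0 <- md_system(rbind(c(2, 2, 2), c(2, 2, 2 + 0.34 * 2^(1 / 6))), 6,
                    c(1L, 1L), sp)
  m0 <- minimize(dim0, ff, ftol = 1e-3)
  expect_equal(m0$system$x, dim0$x, tolerance = 1e-4)
  # overlapping soft-core pair relaxes to finite energy
  ffsc <- set_pair_mode(ff, "water", "water", "softcore")
  ffsc <- set_lambda(ffsc, 0.5)
  over <- md_system(rbind(c(2, 2, 2), c(2, 2, 2.01)), 6, c(1L, 1L), sp)
  m1 <- minimize(over, ffsc, max_steps = 200)
  expect_true(is.finite(m1$energy))
  e0 <- total_energy_forces(over, ffsc)$energy[["total"]]
  expect_lte(m1$energy, e0) # descent contract
})

test_that("MC volume barostat reproduces the virial pressure at the target", {
  fl <- tiny_fluid(n = 60, box = 2.4, sigma = 0.3, eps = 1.0)
  sys <- maxwell_velocities(fl$sys, 300, 5)
  target <- 25 # kJ/mol/nm^3, well above zero so the signal is clear
  spec <- integrator_spec(barostat = mc_barostat(target, interval = 20,
                                                 max_dlnV = 0.04))
  out <- run_segment(sys, fl$ff, spec, 12000, seed = 6, stride = 20)
  rec <- out$records[-(1:150), ]
  p <- virial_pressure(rec, 60, 300)
  # statistical check: generous band, small system
  expect_equal(p, target, tolerance = 0.25)
})
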