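test_that("mixtures realise the requested composition and are reproducible", {
  spec <- reduced_solvent_spec("methanol")
  pure_w <- build_mixture(spec, 0, 80, seed = 1, box = 2.0)
  expect_equal(attr(pure_w, "n_alcohol"), 0)
  expect_true(all(pure_w$species$role[pure_w$sp] == "water"))
  pure_a <- build_mixture(spec, 1, 30, seed = 1, box = 2.0)
  expect_equal(attr(pure_a, "n_water"), 0)
  mix <- build_mixture(spec, 0.25, 400, seed = 2, box = 3.4)
  expect_equal(attr(mix, "n_alcohol"), 100)
  # generators are pure functions of (spec, seed)
  expect_identical(build_mixture(spec, 0.25, 100, seed = 5, box = 2.4)$x,
                   build_mixture(spec, 0.25, 100, seed = 5, box = 2.4)$x)
  # the two-site cosolvent arrives bonded
  spec2 <- reduced_solvent_spec("ethanol")
  mix2 <- build_mixture(spec2, 0.5, 40, seed = 3, box = 2.2)
  expect_equal(attr(mix2, "n_alcohol"), 20)
  expect_equal(nrow(mix2$bonds), 20)
  bl <- sqrt(rowSums((mix2$x[mix2$bonds[, 1], ] -
                        mix2$x[mix2$bonds[, 2], ])^2))
  expect_equal(unname(bl), rep(spec2$bond_r0, 20), tolerance = 1e-9)
})

test_that("biased Rg sampling reproduces the Gaussian product closed form", {
  # harmonic profile times harmonic bias = Gaussian with known moments
  kappa <- 400; c0 <- 0.8
  kb <- 3000; rg0 <- 0.7
  pmf <- analytic_pmf("harmonic", center = c0, kappa = kappa,
                      domain = c(0.3, 1.3))
  win <- list(rg0 = rg0, k_b = kb)
  s <- sample_biased_rg(pmf, win, 40000, seed = 13, n_grid = 8192)
  ktot <- kappa + kb
  mu <- (kappa * c0 + kb * rg0) / ktot
  expect_equal(mean(s), mu, tolerance = 0.002)
  expect_equal(var(s), RT300 / ktot, tolerance = 0.03)
  # a stiff bias collapses the samples onto the window target
  stiff <- sample_biased_rg(pmf, list(rg0 = 0.7, k_b = 1e8), 500, seed = 1)
  expect_lt(sd(stiff), 1e-3)
  # histogram matches the target density (chi-square at alpha = 0.01)
  pmf2 <- analytic_pmf("double_well", weight = 0.45)
  win2 <- list(rg0 = 0.75, k_b = 800)
  s2 <- sample_biased_rg(pmf2, win2, 10000, seed = 7, n_grid = 16384)
  br <- seq(0.4, 1.2, by = 0.04)
  obs <- hist(s2, breaks = br, plot = FALSE)$counts
  dfun <- function(x)
    exp(-(pmf2$fn(x) + 0.5 * win2$k_b * (x - win2$rg0)^2) / RT300)
  pexp <- vapply(seq_len(length(br) - 1), function(i)
    integrate(dfun, br[i], br[i + 1], rel.tol = 1e-9)$value, numeric(1))
  pexp <- pexp / sum(pexp)
  keep <- pexp * 10000 >= 5
  chi <- sum((obs[keep] - 10000 * pexp[keep])^2 / (10000 * pexp[keep]))
  expect_lt(chi, qchisq(0.99, sum(keep) - 1))
})

test_that("double-well construction hits the prescribed collapse free energy", {
  for (dg in c(-4, 0, 2)) {
    pmf <- double_well_pmf(dg)
    # independent quadrature of the constructed profile
    num <- integrate(function(x) exp(-pmf$fn(x) / RT300), 0.4, 0.7,
                     rel.tol = 1e-10)$value
    den <- integrate(function(x) exp(-pmf$fn(x) / RT300), 0.7, 1.2,
                     rel.tol = 1e-10)$value
    expect_equal(-RT300 * log(num / den), dg, tolerance = 1e-4)
  }
})

test_that("Widom insertion oracle obeys ideal-gas and free-volume limits", {
  spec <- reduced_solvent_spec("methanol")
  ff <- mixture_forcefield(spec)
  # ideal gas: no interactions, dG = 0
  sp_id <- spec$species; sp_id$epsilon <- c(0, 0, 0)
  ff_id <- build_forcefield(sp_id)
  set.seed(2)
  frames <- lapply(1:5, function(i)
    md_system(matrix(runif(90, 0, 2), 30, 3), 2, rep(2L, 30), sp_id))
  out <- widom_insertion_oracle(frames, ff_id, "P", 500, seed = 3)
  expect_equal(out$dg, 0)
  # near-hard-sphere limit: acceptance ~ free-volume fraction on a sparse
  # fixture; dG = -RT ln(fraction)
  ff_hs <- mixture_forcefield(spec, wca_polymer_solvent = TRUE)
  ff_hs$eps_ij[] <- 1e6 # effectively hard
  grid <- as.matrix(expand.grid(x = c(0.5, 1.5), y = c(0.5, 1.5),
                                z = c(0.5, 1.5)))
  frame <- md_system(grid, 2, rep(2L, 8), spec$species)
  out2 <- widom_insertion_oracle(list(frame), ff_hs, "P", 40000, seed = 4)
  # excluded sphere around each solvent of radius ~ 2^(1/6) sigma_pw
  rex <- 2^(1 / 6) * (0.4 + 0.3) / 2
  ffree <- 1 - 8 * (4 / 3) * pi * rex^3 / 8
  expect_equal(out2$dg, -RT300 * log(ffree), tolerance = 0.15)
})

test_that("conformer generators hit their targets with intact bonds", {
  for (kind in c("coil", "globule")) {
    conf <- make_conformers(32, kind, seed = 1)
    target <- if (kind == "coil") 1.0 else 0.5
    expect_lte(abs(compute_rg(conf) - target), 0.05 * target)
    bl <- sqrt(rowSums((conf$x[conf$bonds[, 1], ] -
                          conf$x[conf$bonds[, 2], ])^2))
    expect_true(all(bl <= 1.2 * 0.4)) # integrity: no stretched bonds
    expect_identical(make_conformers(32, kind, seed = 1)$x, conf$x)
  }
})

test_that("the reduced cosolvent is enriched at a repulsive wall (surfactant premise)", {
  # slab fixture: a frozen plane of WCA polymer beads spanning the box;
  # the alcohol-like species should accumulate in the wall's first shell
  spec <- reduced_solvent_spec("methanol")
  g <- seq(0.2, 1.8, by = 0.4) # spacing = sigma_p: no core overlap in the wall
  wall <- as.matrix(expand.grid(x = g, y = g, z = 1.0))
  nw <- nrow(wall)
  # solvent packed into the wall-free slab, then shifted clear of the
  # wall; the box is sized so the liquid fills it (no vapour gap)
  mixt <- build_mixture(spec, 0.2, 150, seed = 21, box = c(2, 2, 1.95))
  solv <- sweep(mixt$x, 2, c(0, 0, 1.4), "+")
  sys <- md_system(rbind(wall, solv), c(2, 2, 2.75),
                   c(rep(1L, nw), mixt$sp), spec$species,
                   mol_id = c(rep(1L, nw), mixt$mol_id + 1L))
  ff <- mixture_forcefield(spec, wca_polymer_solvent = TRUE)
  restr <- list(position_restraint(wall, 1e5, seq_len(nw)))
  sys <- minimize(sys, ff, restr, max_steps = 200)$system
  sys <- maxwell_velocities(sys, 300, 22)
  sys <- run_segment(sys, ff, integrator_spec(), 4000, restr, seed = 23,
                     stride = 0)$system
  out <- run_segment(sys, ff, integrator_spec(), 16000, restr, seed = 24,
                     stride = 25, shell_cutoff = 0.55)
  pb <- preferential_binding(out$records)
  expect_gt(pb$gamma, 0)
  expect_gt(pb$gamma, 2 * pb$stderr)
})
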