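test_that("LJ energy and force match the closed form and its roots", {
  pp <- pair_params(0.4, 1.0, "LJ")
  out <- lj_energy_force(c(0.4, 0.4 * 2^(1 / 6), 0.5), pp)
  expect_equal(out$energy[1], 0)                      # LJ root at r = sigma
  expect_equal(out$energy[2], -1.0)                   # minimum depth -eps
  expect_equal(out$force[2], 0, tolerance = 1e-12)
  expect_equal(out$energy[3], ref_lj(0.5, 0.4, 1.0))  # independent evaluation
  # truncation: zero beyond the cutoff
  expect_equal(lj_energy_force(1.5, pp)$energy, 0)
  expect_error(lj_energy_force(-0.1, pp), "positive")
})

test_that("WCA is the shifted repulsive LJ branch, zero beyond the split", {
  pp <- pair_params(0.4, 2.0, "WCA")
  split <- 0.4 * 2^(1 / 6)
  out <- wca_energy_force(c(split, 0.4, split + 0.2, 1.0), pp)
  expect_equal(out$energy[1], 0, tolerance = 1e-12)
  expect_equal(out$force[1], 0, tolerance = 1e-10)
  expect_equal(out$energy[2], 2.0)            # LJ(sigma) = 0 plus shift eps
  expect_equal(out$energy[3:4], c(0, 0))
  expect_equal(out$force[3:4], c(0, 0))
  # non-negative and non-increasing in r
  r <- seq(0.05, 0.6, length.out = 200)
  e <- wca_energy_force(r, pp)$energy
  expect_true(all(e >= 0))
  expect_true(all(diff(e) <= 1e-12))
})

test_that("soft-core coupling interpolates WCA and keeps dU/dlambda finite", {
  pp <- pair_params(0.35, 2.0, "softcore")
  sc <- softcore_params() # alpha 0.5, p 1, sigma 0.3
  r <- c(0.05, 0.2, 0.3, 0.38, 0.5)
  # end-state identity at lambda = 1
  expect_equal(softcore_energy_dudl(r, pp, 1, sc)$energy,
               wca_energy_force(r, pp)$energy, tolerance = 1e-12)
  # vanishing, finite-gradient start state (even near r = 0)
  at0 <- softcore_energy_dudl(c(1e-9, 0.1), pp, 0, sc)
  expect_equal(at0$energy, c(0, 0))
  expect_true(all(is.finite(at0$dudl)))
  expect_error(softcore_energy_dudl(0.3, pp, 1.2, sc), "lam")
  # dU/dlambda matches a central finite difference over lambda
  h <- 1e-7
  for (lam in c(0.1, 0.5, 0.9)) {
    fd <- (softcore_energy_dudl(0.3, pp, lam + h, sc)$energy -
             softcore_energy_dudl(0.3, pp, lam - h, sc)$energy) / (2 * h)
    expect_equal(softcore_energy_dudl(0.3, pp, lam, sc)$dudl, fd,
                 tolerance = 1e-6)
  }
})

test_that("analytic pair forces equal -dU/dr at random radii", {
  set.seed(7)
  r <- runif(100, 0.18, 1.3)
  h <- 1e-7
  pp_lj <- pair_params(0.4, 1.3, "LJ")
  pp_wca <- pair_params(0.4, 1.3, "WCA")
  sc <- softcore_params()
  for (case in list(
    list(f = function(r) lj_energy_force(r, pp_lj)$energy,
         g = function(r) lj_energy_force(r, pp_lj)$force),
    list(f = function(r) wca_energy_force(r, pp_wca)$energy,
         g = function(r) wca_energy_force(r, pp_wca)$force),
    list(f = function(r) softcore_energy_dudl(r, pp_wca, 0.6, sc)$energy,
         g = function(r) softcore_energy_dudl(r, pp_wca, 0.6, sc)$force))) {
    keep <- abs(r - 1.4) > 1e-3 & abs(r - 0.4 * 2^(1 / 6)) > 1e-3
    fd <- -(case$f(r[keep] + h) - case$f(r[keep] - h)) / (2 * h)
    an <- case$g(r[keep])
    expect_equal(an, fd, tolerance = 1e-6)
  }
})

test_that("Lorentz-Berthelot mixing with lambda scaling builds the pair table", {
  sp <- dplyr::bind_rows(species("P", 0.4, 1.0, 40, "polymer"),
                         species("W", 0.3, 2.89, 18, "water"),
                         species("A", 0.45, 3.0, 32, "alcohol"))
  # identity scaling: plain Lorentz-Berthelot
  ff0 <- build_forcefield(sp, lambda_scaling(1, 1))
  expect_equal(ff0$sigma_ij["P", "W"], 0.35)
  expect_equal(ff0$eps_ij["P", "W"], sqrt(2.89))
  # two identical species mix to themselves
  expect_equal(ff0$sigma_ij["W", "W"], 0.3)
  expect_equal(ff0$eps_ij["W", "W"], 2.89)
  # production scaling multiplies well depths, leaves diameters alone
  ff <- build_forcefield(sp, lambda_scaling(1.095, 0.949))
  expect_equal(ff$eps_ij["P", "W"], 1.095 * sqrt(2.89))
  expect_equal(ff$eps_ij["P", "A"], 0.949 * sqrt(3.0))
  expect_equal(ff$sigma_ij["P", "A"], ff0$sigma_ij["P", "A"])
  expect_equal(ff$eps_ij["W", "A"], ff0$eps_ij["W", "A"])
  # repulsive-only polymer-(co)solvent variant
  ffw <- build_forcefield(sp, wca_polymer_solvent = TRUE)
  expect_equal(ffw$mode_ij["P", "W"], 1L)
  expect_equal(ffw$mode_ij["P", "A"], 1L)
  expect_equal(ffw$mode_ij["W", "A"], 0L)
  bad <- sp; bad$role[2] <- "oil"
  expect_error(species("X", 0.3, 1, 18, "oil"))
  expect_error(build_forcefield(bad), "role")
})

test_that("soft-core TI over lambda recovers the exact coupling energy of a frozen pair", {
  # at fixed coordinates the lambda integral of dU/dlambda telescopes to
  # U(1) - U(0); checked with fine trapezoidal quadrature per radius
  pp <- pair_params(0.37, 2.5, "softcore")
  sc <- softcore_params()
  lam <- seq(0, 1, length.out = 4001)
  for (r in c(0.22, 0.3, 0.4)) {
    d <- softcore_energy_dudl(rep(r, length(lam)), pp, 0, sc)
    dudl <- vapply(lam, function(l)
      softcore_energy_dudl(r, pp, l, sc)$dudl, numeric(1))
    integral <- sum((dudl[-1] + dudl[-length(lam)]) / 2 * diff(lam))
    expect_equal(integral, wca_energy_force(r, pp)$energy, tolerance = 1e-4)
  }
})
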