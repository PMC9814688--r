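test_that("window generation produces the inclusive grid with distinct seeds", {
  w <- generate_windows(0.4, 1.2, 0.025, master_seed = 7)
  expect_equal(nrow(w), 33)
  expect_equal(w$rg0[1], 0.4)
  expect_equal(w$rg0[33], 1.2)
  expect_equal(diff(w$rg0), rep(0.025, 32))
  expect_equal(anyDuplicated(w$seed), 0)
  expect_equal(nrow(generate_windows(0.4, 0.4, 0.025)), 1)
  expect_error(generate_windows(0.4, 0.5, 0.2), "spacing")
})

test_that("WHAM with a single unbiased window is Boltzmann inversion", {
  set.seed(21)
  rg <- rnorm(20000, 0.7, 0.08)
  w <- generate_windows(0.7, 0.7, 0.01, k_b = 0, master_seed = 1)
  h <- histogram_set(list(rg), w, bin_width = 0.02)
  pmf <- wham_solve(h, n_boot = 0)
  counts <- h$counts[, 1]
  ref <- -RT300 * log(counts / sum(counts))
  ref <- ref - min(ref[counts > 0])
  expect_equal(pmf$w[counts > 0], ref[counts > 0], tolerance = 1e-8)
})

test_that("WHAM is invariant to window order and per-window count rescaling", {
  pmf_true <- analytic_pmf("double_well", weight = 0.4)
  w <- generate_windows(0.45, 1.15, 0.07, k_b = 2000, master_seed = 3)
  samples <- lapply(seq_len(nrow(w)), function(i)
    sample_biased_rg(pmf_true, w[i, ], 4000, seed = w$seed[i]))
  h <- histogram_set(samples, w, bin_width = 0.02)
  base <- wham_solve(h, n_boot = 0)
  # duplicating every window's data leaves the profile unchanged
  h2 <- h; h2$counts <- h$counts * 2
  expect_equal(wham_solve(h2, n_boot = 0)$w, base$w, tolerance = 1e-6)
  # reordering windows leaves the profile unchanged
  ord <- rev(seq_len(nrow(w)))
  h3 <- histogram_set(samples[ord], w[ord, ], bin_width = 0.02,
                      range = range(h$bin_edges))
  expect_equal(wham_solve(h3, n_boot = 0)$w, base$w, tolerance = 1e-6)
})

test_that("WHAM recovers a prescribed double-well profile from biased samples", {
  pmf_true <- double_well_pmf(-2)
  w <- generate_windows(0.4, 1.2, 0.05, k_b = 5000, n_prod_steps = 1,
                        master_seed = 11)
  samples <- lapply(seq_len(nrow(w)), function(i)
    sample_biased_rg(pmf_true, w[i, ], 8000, seed = w$seed[i]))
  h <- histogram_set(samples, w, bin_width = 0.01)
  pmf <- wham_solve(h, n_boot = 10, seed = 2)
  well <- rowSums(h$counts) > 200
  resid <- pmf$w[well] - pmf_true$fn(pmf$rg[well])
  resid <- resid - mean(resid) # profiles agree up to an additive constant
  expect_lt(sqrt(mean(resid^2)), 0.1 * RT300)
})

test_that("two-state integral reproduces closed forms and quadrature oracle", {
  # uniform profile on [0.4, 1.2] with the cut at 0.7
  pmf <- pmf_profile(seq(0.4, 1.2, 0.01), rep(0, 81))
  dg <- collapse_free_energy(pmf, 0.7)
  expect_equal(dg$dg, -RT300 * log(0.3 / 0.5), tolerance = 1e-9)
  # symmetric double well, cut at the symmetry point
  rgs <- seq(0.3, 1.1, 0.005)
  wsym <- 40 * ((rgs - 0.7)^2 - 0.04)^2 / 0.04^2
  expect_lt(abs(collapse_free_energy(pmf_profile(rgs, wsym), 0.7)$dg), 1e-6)
  # tabulated profile vs an independent high-resolution quadrature of the
  # same piecewise-linear interpolant
  set.seed(31)
  rgt <- seq(0.4, 1.2, 0.02)
  wt <- 3 * sin(4 * rgt) + 5 * (rgt - 0.8)^2
  wt <- wt - min(wt)
  p2 <- pmf_profile(rgt, wt)
  # exact segment-wise integral of exp(-w/RT) for piecewise-linear w
  seg_exact <- function(rg, w, lo, hi) {
    grid <- sort(unique(c(lo, hi, rg[rg > lo & rg < hi])))
    wv <- approx(rg, w, xout = grid)$y
    tot <- 0
    for (i in seq_len(length(grid) - 1)) {
      b <- (wv[i + 1] - wv[i]) / (grid[i + 1] - grid[i])
      tot <- tot + if (abs(b) < 1e-12)
        exp(-wv[i] / RT300) * (grid[i + 1] - grid[i])
      else (exp(-wv[i] / RT300) - exp(-wv[i + 1] / RT300)) * RT300 / b
    }
    tot
  }
  w0 <- p2$w
  oracle <- -RT300 * log(seg_exact(rgt, w0, 0.4, 0.7) /
                           seg_exact(rgt, w0, 0.7, 1.2))
  expect_equal(collapse_free_energy(p2, 0.7)$dg, oracle, tolerance = 1e-6)
  # anchor invariance and monotone response to deepening the globule basin
  p3 <- p2; p3$w <- p3$w + 5
  expect_equal(collapse_free_energy(p3, 0.7)$dg,
               collapse_free_energy(p2, 0.7)$dg, tolerance = 1e-9)
  deeper <- p2$w - 2 * exp(-(p2$rg - 0.55)^2 / 0.01)
  expect_lt(collapse_free_energy(pmf_profile(rgt, deeper), 0.7)$dg,
            collapse_free_energy(p2, 0.7)$dg)
  expect_error(collapse_free_energy(p2, 1.3), "outside")
})

test_that("umbrella campaign on a vacuum polymer is seed-robust and checkpointable", {
  poly <- make_conformers(10, "coil", seed = 6, target_rg = 0.42)
  ff <- build_forcefield(poly$species)
  w <- generate_windows(0.32, 0.56, 0.04, k_b = 5000, n_equil_steps = 300,
                        n_prod_steps = 2500, master_seed = 5)
  spec <- integrator_spec()
  camp <- umbrella_campaign(poly, ff, w, spec, stride = 5, bin_width = 0.015,
                            rg_cut = 0.44, n_boot = 20)
  w2 <- w; w2$seed <- w$seed + 1000
  camp2 <- umbrella_campaign(poly, ff, w2, spec, stride = 5,
                             bin_width = 0.015, rg_cut = 0.44, n_boot = 20)
  # two independent seeds agree within combined bootstrap errors (3 sigma)
  se <- sqrt(camp$dg$stderr^2 + camp2$dg$stderr^2)
  expect_lt(abs(camp$dg$dg - camp2$dg$dg), 3 * se + 0.5)
  # same seeds reproduce bit-identically (restartability)
  camp3 <- umbrella_campaign(poly, ff, w, spec, stride = 5,
                             bin_width = 0.015, rg_cut = 0.44, n_boot = 20)
  expect_identical(camp$records, camp3$records)
})

test_that("umbrella + WHAM matches direct Monte Carlo for tethered ideal beads", {
  # ideal (non-interacting) beads tethered to the box centre by harmonic
  # springs: both the dynamics and plain Monte Carlo sample the same
  # product-Gaussian ensemble, so the unbiased Rg density is known by
  # direct sampling
  n <- 6; L <- 4; kappa <- 50
  sd_t <- sqrt(RT300 / kappa)
  set.seed(17)
  rg_mc <- replicate(40000,
    compute_rg(matrix(rnorm(3 * n, L / 2, sd_t), n, 3), seq_len(n)))
  sp <- species("I", 0.3, 0.0, 20, "water") # ideal: no interactions
  sys <- md_system(matrix(rnorm(3 * n, L / 2, sd_t), n, 3), L, rep(1L, n),
                   sp)
  ff <- build_forcefield(sp)
  tether <- position_restraint(matrix(L / 2, n, 3), kappa, seq_len(n))
  w <- generate_windows(0.25, 0.65, 0.08, k_b = 2000, n_equil_steps = 400,
                        n_prod_steps = 6000, master_seed = 9)
  camp <- umbrella_campaign(sys, ff, w, integrator_spec(dt = 0.004),
                            stride = 4, bin_width = 0.025, rg_cut = 0.45,
                            n_boot = 10, restraints = list(tether))
  edges <- camp$histograms$bin_edges
  cnt <- hist(rg_mc[rg_mc >= min(edges) & rg_mc <= max(edges)],
              breaks = edges, plot = FALSE)$counts
  ref <- -RT300 * log(cnt / sum(cnt))
  ok <- cnt > 500 & is.finite(camp$pmf$w)
  resid <- camp$pmf$w[ok] - ref[ok]
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.35 * RT300)
})
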