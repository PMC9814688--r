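test_that("SASA reproduces sphere geometry", {
  one <- shrake_rupley_sasa(matrix(0, 1, 3), radii = 0.2, probe = 0.14,
                            n_points = 960)
  expect_equal(one$total, 4 * pi * 0.34^2, tolerance = 0.01)
  # two (essentially) coincident spheres expose one sphere's area; each
  # centre buries the other's inner hemisphere
  two <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(1e-4, 0, 0)), radii = 0.2,
                            probe = 0.14, n_points = 960)
  expect_equal(two$total, 4 * pi * 0.34^2, tolerance = 0.02)
  # per-particle areas bounded by the full sphere, total is their sum
  set.seed(3)
  x <- matrix(rnorm(45, sd = 0.3), 15, 3)
  s <- shrake_rupley_sasa(x, radii = 0.2)
  expect_true(all(s$per_particle >= 0))
  expect_true(all(s$per_particle <= 4 * pi * 0.34^2 + 1e-9))
  expect_equal(s$total, sum(s$per_particle))
  expect_error(shrake_rupley_sasa(x, radii = 0.2, n_points = 8),
               "n_points")
})

test_that("an extended chain exposes more surface than a compact cluster", {
  chain <- make_conformers(32, "rod")
  cluster <- make_conformers(32, "globule", seed = 2)
  expect_gt(shrake_rupley_sasa(chain)$total,
            shrake_rupley_sasa(cluster)$total)
})

test_that("first-shell counts match a hand-built frame and a brute-force loop", {
  spec <- reduced_solvent_spec("methanol")
  sp <- spec$species
  # polymer bead at the centre, 3 waters at 0.3 nm, 1 alcohol at 0.8 nm
  x <- rbind(c(1, 1, 1), c(1.3, 1, 1), c(1, 1.3, 1), c(1, 1, 1.3),
             c(1.8, 1, 1))
  sys <- md_system(x, 2.4, c(1L, 2L, 2L, 2L, 3L), sp,
                   mol_id = 1:5)
  counts <- first_shell_counts(sys, 0.5)
  expect_equal(unname(counts[c("n_water", "n_alcohol")]), c(3L, 0L))
  expect_equal(unname(first_shell_counts(sys, 0)[1:2]), c(0L, 0L))
  expect_equal(unname(first_shell_counts(sys, 0.9)[1:2]), c(3L, 1L))
  # brute-force oracle on a random mixture (minimum image)
  mix <- build_mixture(spec, 0.3, 40, seed = 9, box = 2.2,
                       polymer = make_conformers(6, "coil", seed = 1,
                                                 target_rg = 0.4))
  got <- first_shell_counts(mix, 0.55)
  sel <- polymer_selection(mix)
  sol <- setdiff(seq_len(nrow(mix$x)), sel)
  inshell <- vapply(sol, function(i) {
    d <- sweep(mix$x[sel, , drop = FALSE], 2, mix$x[i, ])
    d <- d - sweep(round(sweep(d, 2, mix$box, "/")), 2, mix$box, "*")
    any(rowSums(d^2) <= 0.55^2)
  }, logical(1))
  mol_in <- tapply(inshell, mix$mol_id[sol], any)
  role <- mix$mol_role[as.integer(names(mol_in))]
  expect_equal(unname(got[["n_water"]]), sum(mol_in[role == 1]))
  expect_equal(unname(got[["n_alcohol"]]), sum(mol_in[role == 2]))
})

test_that("preferential binding coefficient matches hand arithmetic and symmetry", {
  rec <- tibble::tibble(na_shell = c(4, 6), nw_shell = c(10, 8),
                        na_bulk = c(20, 18), nw_bulk = c(80, 82))
  pb <- preferential_binding(rec, n_blocks = 2)
  expect_equal(pb$gamma, mean(c(4 - 20 / 80 * 10, 6 - 18 / 82 * 8)))
  # ideal mixed solvent with no preference: gamma ~ 0
  set.seed(5)
  n <- 4000
  tot_shell <- 30; tot_bulk <- 120
  a_sh <- rbinom(n, tot_shell, 0.25)
  a_blk <- rbinom(n, tot_bulk, 0.25)
  rec2 <- tibble::tibble(na_shell = a_sh, nw_shell = tot_shell - a_sh,
                         na_bulk = a_blk, nw_bulk = tot_bulk - a_blk)
  pb2 <- preferential_binding(rec2)
  expect_lt(abs(pb2$gamma), 4 * pb2$stderr + 0.05)
  # swapping species labels (and inverting the composition) flips the sign
  rec3 <- tibble::tibble(na_shell = rec$nw_shell, nw_shell = rec$na_shell,
                         na_bulk = rec$nw_bulk, nw_bulk = rec$na_bulk)
  pb3 <- preferential_binding(rec3, n_blocks = 2)
  expect_equal(sign(pb3$gamma), -sign(pb$gamma))
})

test_that("saturation analysis finds the Langmuir slope threshold and rejects linear profiles", {
  x <- seq(0.02, 0.5, by = 0.02)
  K <- 12; nmax <- 40
  prof <- tibble::tibble(x_alcohol = x, n_shell = nmax * K * x / (1 + K * x))
  out <- saturation_concentration(prof)
  x_star <- (1 / sqrt(0.1) - 1) / K # closed-form 10%-slope crossing
  expect_lte(abs(out$x_sat - x_star), 0.02) # within one grid step
  expect_equal(out$K, K, tolerance = 1e-4)
  # scale invariance of the threshold
  prof2 <- prof; prof2$n_shell <- prof2$n_shell * 3.7
  expect_equal(saturation_concentration(prof2)$x_sat, out$x_sat)
  # strictly linear profile saturates nowhere inside the grid
  lin <- tibble::tibble(x_alcohol = x, n_shell = 5 * x)
  expect_warning(out_lin <- saturation_concentration(lin), "satur")
  expect_true(is.na(out_lin$x_sat))
})

test_that("SASA scaling exponents match rod and sphere geometry, coil > globule", {
  sc <- sasa_scaling(c(16, 32, 64, 128), seed = 2, kinds = c("rod", "globule"),
                     n_points = 240)
  expect_equal(sc$alpha_coil, 1, tolerance = 0.08)     # rod: area ~ N
  # compact packing approaches the volume-to-surface exponent 2/3 from
  # below (finite-N surface roughness)
  expect_lt(abs(sc$alpha_globule - 2 / 3), 0.15)
  sc2 <- sasa_scaling(c(16, 32, 64), seed = 2, n_points = 240)
  expect_gt(sc2$alpha_coil, sc2$alpha_globule)
})

test_that("RDF-based shell cutoff finds the first minimum", {
  rdf <- tibble::tibble(r = seq(0.05, 1.0, 0.05),
                        g = c(0, 0, 0, 0.2, 1.8, 2.4, 1.6, 0.8, 0.6, 0.9,
                              1.1, 1.05, 1, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(shell_cutoff_from_rdf(rdf), 0.45)
  flat <- tibble::tibble(r = seq(0.05, 1, 0.05), g = rep(0, 20))
  expect_equal(shell_cutoff_from_rdf(flat), 0.55)
})
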