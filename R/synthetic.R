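#' Reduced binary solvent specification
#'
#' The desk-scale stand-in for an atomistic water/alcohol mixture: a one-site
#' water-like liquid plus a one-site "methanol-like" or two-site bonded
#' "ethanol-like" cosolvent. Cohesion that in reality comes from hydrogen
#' bonding is folded into the LJ well depths; the cosolvent is larger and
#' less cohesive than water and the water-alcohol cross well depth is scaled
#' by `xi_wa < 1`, which together make it interfacially active (the
#' surfactant premise). Per-molecule liquid volumes `v_w`, `v_a` set NVT box
#' sizes; they were fixed once from barostatted pure-liquid runs of this
#' model at 300 K and 1 atm.
#'
#' @param alcohol `"methanol"` or `"ethanol"`.
#' @param xi_wa Water-alcohol cross-interaction factor.
#' @param v_w,v_a Per-molecule liquid volumes (nm^3).
#' @param bond_r0,bond_k Ethanol-like site-site bond (nm, kJ/mol/nm^2).
#' @return A `reduced_solvent_spec`.
#' @export
reduced_solvent_spec <- function(alcohol = c("methanol", "ethanol"),
                                 xi_wa = 0.90, v_w = 0.0321,
                                 v_a = NULL, bond_r0 = 0.25,
                                 bond_k = 20000) {
  alcohol <- match.arg(alcohol)
  sp <- default_species(alcohol)
  sites <- if (alcohol == "ethanol") 2L else 1L
  if (is.null(v_a)) v_a <- if (alcohol == "methanol") 0.120 else 0.121
  structure(list(alcohol = alcohol, species = sp, sites = sites,
                 xi_wa = xi_wa, v_w = v_w, v_a = v_a, v_p = 0.0335,
                 bond_r0 = bond_r0, bond_k = bond_k),
            class = "reduced_solvent_spec")
}

#' Build a solvent mixture, optionally around a polymer
#'
#' Random sequential insertion with overlap rejection at the requested
#' composition `X_Alcohol = N_Alcohol / (N_Alcohol + N_Water)`. Molecule
#' counts use largest-remainder rounding. If `box` is missing it is sized
#' from the per-molecule liquid volumes in `spec`.
#'
#' @param spec A [reduced_solvent_spec()].
#' @param x_alcohol Cosolvent mole fraction in \[0, 1\].
#' @param n_solvent Total number of solvent molecules.
#' @param seed Integer seed.
#' @param box Optional box edge (nm, scalar or length 3).
#' @param polymer Optional `md_system` holding a polymer conformation to
#'   embed (centred in the box).
#' @return An `md_system` whose species table is (P, W, A...) so one force
#'   field covers systems with and without the polymer.
#' @export
build_mixture <- function(spec, x_alcohol, n_solvent, seed = 1L, box = NULL,
                          polymer = NULL) {
  stopifnot(x_alcohol >= 0, x_alcohol <= 1, n_solvent >= 0)
  n_a <- round(x_alcohol * n_solvent)
  n_w <- n_solvent - n_a
  np <- if (is.null(polymer)) 0L else nrow(polymer$x)
  if (is.null(box)) {
    # 6% headroom for random packing; NPT pre-equilibration recompresses
    vol <- 1.06 * (n_w * spec$v_w + n_a * spec$v_a + np * spec$v_p)
    box <- rep(max(vol, 1e-3)^(1 / 3), 3)
  }
  if (length(box) == 1) box <- rep(box, 3)
  set.seed(seed)
  sp_tbl <- spec$species
  sig <- sp_tbl$sigma
  # site lists start with the (centred) polymer
  xs <- NULL; spid <- integer(0); mol <- integer(0)
  bonds <- NULL
  if (!is.null(polymer)) {
    xc <- sweep(polymer$x, 2, colMeans(polymer$x))
    xs <- sweep(xc, 2, box / 2, "+")
    spid <- rep(1L, np)
    mol <- rep(1L, np)
    bonds <- polymer$bonds
  }
  nmol <- if (np > 0) 1L else 0L
  insert_site <- function(pos, sp_new) {
    # reject if closer than 0.8 sigma_ij to any accepted site (min image)
    if (!is.null(xs) && nrow(xs) > 0) {
      d <- sweep(xs, 2, pos)
      d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
      r2 <- rowSums(d^2)
      dmin <- (0.80 * (sig[spid] + sig[sp_new]) / 2)^2
      all(r2 > dmin)
    } else TRUE
  }
  place <- c(rep(3L, n_a), rep(2L, n_w)) # alcohol first (harder to place)
  for (s in place) {
    ok <- FALSE
    for (attempt in 1:2000) {
      cm <- runif(3) * box
      if (s == 3L && spec$sites == 2L) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        p1 <- cm + u * spec$bond_r0 / 2
        p2 <- cm - u * spec$bond_r0 / 2
        if (insert_site(p1, 3L) && insert_site(p2, 3L)) {
          i0 <- length(spid)
          xs <- rbind(xs, p1, p2); spid <- c(spid, 3L, 3L)
          nmol <- nmol + 1L; mol <- c(mol, nmol, nmol)
          bonds <- rbind(bonds, c(i0 + 1, i0 + 2, spec$bond_r0, spec$bond_k))
          ok <- TRUE
        }
      } else {
        if (insert_site(cm, s)) {
          xs <- rbind(xs, cm); spid <- c(spid, s)
          nmol <- nmol + 1L; mol <- c(mol, nmol)
          ok <- TRUE
        }
      }
      if (ok) break
    }
    if (!ok) stop("solvent insertion failed; the box is too small/dense")
  }
  if (is.null(xs)) xs <- matrix(0, 0, 3)
  angles <- if (!is.null(polymer)) polymer$angles else NULL
  sys <- md_system(xs, box, spid, sp_tbl, bonds = bonds, angles = angles,
                   mol_id = mol)
  attr(sys, "x_alcohol") <- if (n_solvent > 0) n_a / n_solvent else NA_real_
  attr(sys, "n_water") <- n_w
  attr(sys, "n_alcohol") <- n_a
  sys
}

#' Force field for a reduced-solvent system
#'
#' Convenience wrapper applying the spec's cross-interaction factor.
#'
#' @param spec A [reduced_solvent_spec()].
#' @param scaling A [lambda_scaling()].
#' @param wca_polymer_solvent Repulsive-only polymer-(co)solvent pairs?
#' @param ... Passed to [build_forcefield()].
#' @export
mixture_forcefield <- function(spec, scaling = lambda_scaling(),
                               wca_polymer_solvent = FALSE, ...) {
  build_forcefield(spec$species, scaling = scaling,
                   wca_polymer_solvent = wca_polymer_solvent,
                   xi_wa = spec$xi_wa, ...)
}


#' Box edge for a solvated conformer
#'
#' Cubic edge covering the conformer's largest pairwise extent plus a
#' solvent clearance on each side.
#'
#' @param conformer `md_system` polymer snapshot.
#' @param clearance Clearance (nm) per side.
#' @export
conformer_box <- function(conformer, clearance = 0.35) {
  ext <- max(stats::dist(conformer$x))
  rep(ext + 2 * clearance, 3)
}

#' Solvent count filling a box at liquid density
#'
#' Number of solvent molecules of composition `x_alcohol` that fills the
#' box at the model's liquid molar volumes, with a small packing headroom
#' (the barostat restores the equilibrium density).
#'
#' @param spec A [reduced_solvent_spec()].
#' @param x_alcohol Cosolvent mole fraction.
#' @param box Box edges (nm).
#' @param n_poly_beads Polymer beads already in the box.
#' @param fill Fill fraction (default 0.95).
#' @export
solvent_count_for_box <- function(spec, x_alcohol, box, n_poly_beads = 0,
                                  fill = 0.95) {
  if (length(box) == 1) box <- rep(box, 3)
  v <- prod(box) - n_poly_beads * spec$v_p
  max(0L, floor(fill * v /
                  ((1 - x_alcohol) * spec$v_w + x_alcohol * spec$v_a)))
}

# ---------------------------------------------------------------------------
# analytic PMFs and biased R_g samples (WHAM validation scaffolding)

#' Analytic free-energy profile along R_g
#'
#' Test scaffolding with a known w(R_g): `"uniform"`, `"harmonic"`,
#' `"double_well"` (a two-Gaussian probability mixture, giving two minima
#' separated by a barrier) or `"tabulated"`.
#'
#' @param form Functional form tag.
#' @param domain R_g domain (nm).
#' @param temperature Temperature (K) used by the double-well form.
#' @param centers,widths,weight Double-well component centres/SDs (globule
#'   first) and globule mixture weight.
#' @param center,kappa Harmonic centre and curvature.
#' @param rg,w Tabulated knots.
#' @return An `analytic_pmf` object: a list with a vectorised `fn(rg)` and
#'   the domain.
#' @export
analytic_pmf <- function(form = c("double_well", "harmonic", "uniform",
                                  "tabulated"),
                         domain = c(0.4, 1.2), temperature = 300,
                         centers = c(0.5, 1.0), widths = c(0.05, 0.08),
                         weight = 0.5, center = 0.7, kappa = 100,
                         rg = NULL, w = NULL) {
  form <- match.arg(form)
  RT <- thermal_energy(temperature)
  fn <- switch(form,
    uniform = function(x) rep(0, length(x)),
    harmonic = function(x) 0.5 * kappa * (x - center)^2,
    double_well = function(x) {
      dens <- weight * stats::dnorm(x, centers[1], widths[1]) +
        (1 - weight) * stats::dnorm(x, centers[2], widths[2])
      -RT * log(dens)
    },
    tabulated = {
      stopifnot(!is.null(rg), !is.null(w))
      stats::approxfun(rg, w, rule = 2)
    })
  structure(list(form = form, fn = fn, domain = domain,
                 temperature = temperature),
            class = "analytic_pmf")
}

#' Double-well profile with a prescribed collapse free energy
#'
#' Solves for the globule mixture weight such that the two-state integral
#' (cut at `rg_cut`) of the constructed profile equals `dg_target` exactly
#' (to quadrature resolution).
#'
#' @param dg_target Desired collapse free energy (kJ/mol).
#' @param rg_cut Coil/globule cut (nm).
#' @param temperature Temperature (K).
#' @param ... Passed to [analytic_pmf()] (centres, widths, domain).
#' @export
double_well_pmf <- function(dg_target, rg_cut = 0.7, temperature = 300, ...) {
  f <- function(q) {
    pmf <- analytic_pmf("double_well", weight = q, temperature = temperature,
                        ...)
    pmf_dg(pmf, rg_cut) - dg_target
  }
  q <- uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  analytic_pmf("double_well", weight = q, temperature = temperature, ...)
}

# two-state integral of an analytic pmf on a fine grid (internal; tests use
# an independent quadrature oracle)
pmf_dg <- function(pmf, rg_cut, n = 8192) {
  RT <- thermal_energy(pmf$temperature)
  trap <- function(lo, hi) {
    x <- seq(lo, hi, length.out = n)
    y <- exp(-pmf$fn(x) / RT)
    sum((y[-1] + y[-n]) / 2 * diff(x))
  }
  -RT * log(trap(pmf$domain[1], rg_cut) / trap(rg_cut, pmf$domain[2]))
}

#' Draw biased R_g samples from an analytic profile
#'
#' Samples from the density proportional to
#' `exp(-(w(rg) + V_window(rg)) / RT)` by inverse-CDF interpolation on a
#' fine grid; used to validate WHAM against a known answer.
#'
#' @param pmf An [analytic_pmf()].
#' @param window A row/list with `rg0` and `k_b` (see [generate_windows()]).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param temperature Temperature (K).
#' @param n_grid Grid resolution.
#' @param stratified Use stratified uniforms (one jittered draw per
#'   probability stratum)? The marginal distribution is unchanged but
#'   histogram noise drops far below iid sampling, which sharpens
#'   estimator-recovery checks.
#' @return Numeric vector of R_g samples.
#' @export
sample_biased_rg <- function(pmf, window, n, seed = 1L, temperature = 300,
                             n_grid = 4096, stratified = FALSE) {
  RT <- thermal_energy(temperature)
  x <- seq(pmf$domain[1], pmf$domain[2], length.out = n_grid)
  logd <- -(pmf$fn(x) + 0.5 * window$k_b * (x - window$rg0)^2) / RT
  d <- exp(logd - max(logd))
  # trapezoid CDF with linear interpolation inside intervals
  seg <- (d[-1] + d[-n_grid]) / 2 * diff(x)
  cdf <- c(0, cumsum(seg)) / sum(seg)
  set.seed(seed)
  u <- if (stratified) (sample.int(n) - runif(n)) / n else runif(n)
  idx <- findInterval(u, cdf, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx >= n_grid] <- n_grid - 1
  frac <- (u - cdf[idx]) / pmax(cdf[idx + 1] - cdf[idx], 1e-300)
  x[idx] + frac * (x[idx + 1] - x[idx])
}

# ---------------------------------------------------------------------------
# Widom insertion oracle

#' Widom test-particle insertion estimate of an insertion free energy
#'
#' Brute-force oracle for thermodynamic integration:
#' `dG = -RT ln < exp(-beta dU) >` over uniform random insertions of a ghost
#' site into frozen solvent configurations. Valid for small cavities only
#' (the estimator degenerates when almost every insertion overlaps).
#'
#' @param frames List of `md_system` frames (without the ghost).
#' @param ff `forcefield` whose species table contains the ghost species.
#' @param ghost Name or index of the ghost species in `ff$species`.
#' @param n_insertions Insertions per frame.
#' @param seed Integer seed.
#' @param temperature Temperature (K).
#' @param n_blocks Blocks (over frames) for the standard error.
#' @return List with `dg`, `stderr`, `n_effective`.
#' @export
widom_insertion_oracle <- function(frames, ff, ghost, n_insertions = 1000,
                                   seed = 1L, temperature = 300,
                                   n_blocks = 5) {
  if (is.character(ghost)) ghost <- match(ghost, ff$species$name)
  stopifnot(!is.na(ghost), length(frames) >= 1)
  RT <- thermal_energy(temperature)
  set.seed(seed)
  bolt <- lapply(frames, function(fr) {
    pos <- matrix(runif(3 * n_insertions), ncol = 3)
    pos <- sweep(pos, 2, fr$box, "*")
    u <- cpp_insertion_energy(fr$x, fr$box, fr$sp - 1L, ff$sigma_ij,
                              ff$eps_ij, ff$mode_ij,
                              effective_cutoff(ff, fr$box), ff$lambda,
                              ff$softcore$alpha, ff$softcore$p,
                              ff$softcore$sigma_sc, ghost - 1L, pos)
    exp(-u / RT)
  })
  mb <- vapply(bolt, mean, numeric(1))
  dg <- -RT * log(mean(mb))
  blk <- split(mb, cut(seq_along(mb), n_blocks, labels = FALSE))
  est <- vapply(blk, function(b) -RT * log(mean(b)), numeric(1))
  list(dg = dg, stderr = stats::sd(est) / sqrt(length(est)),
       n_effective = sum(vapply(bolt, function(b) sum(b)^2 / sum(b^2),
                                numeric(1))))
}

# ---------------------------------------------------------------------------
# conformer generation

#' Generate coil, globule or rod polymer conformations
#'
#' `"coil"`: self-avoiding correlated random walk whose bending persistence
#' is tuned until the radius of gyration hits the target within 5%.
#' `"globule"`: compact cluster-grown chain whose site spacing is tuned the
#' same way. `"rod"`: straight tangent-sphere chain (geometric reference).
#' Default targets follow the most probable states of the 32-bead chain
#' (coil 1.0 nm, globule 0.5 nm) scaled as N^(3/5) and N^(1/3) respectively.
#'
#' @param n_beads Number of beads.
#' @param kind `"coil"`, `"globule"` or `"rod"`.
#' @param seed Integer seed.
#' @param target_rg Target R_g (nm); NULL uses the default scaling law.
#' @param r0 Bond length (nm).
#' @param topology Passed to [polymer_topology()] as extra arguments.
#' @return An `md_system` (vacuum box) with polymer topology.
#' @export
make_conformers <- function(n_beads, kind = c("coil", "globule", "rod"),
                            seed = 1L, target_rg = NULL, r0 = 0.4,
                            topology = list()) {
  kind <- match.arg(kind)
  if (is.null(target_rg)) {
    target_rg <- switch(kind,
      coil = 1.0 * (n_beads / 32)^0.6,
      globule = 0.5 * (n_beads / 32)^(1 / 3),
      rod = NA_real_)
  }
  x <- switch(kind,
    rod = cbind(0, 0, (seq_len(n_beads) - 1) * r0),
    coil = grow_coil(n_beads, target_rg, r0, seed),
    globule = grow_globule(n_beads, target_rg, r0, seed))
  topo <- do.call(polymer_topology, c(list(n_beads = n_beads, r0 = r0),
                                      topology))
  box <- max(20, 4 * n_beads * r0)
  sys <- md_system(x, box, rep(1L, n_beads), default_species("methanol"),
                   bonds = topo$bonds, angles = topo$angles,
                   mol_id = rep(1L, n_beads))
  attr(sys, "kind") <- kind
  attr(sys, "target_rg") <- target_rg
  sys
}

# correlated self-avoiding walk; persistence g tuned by bisection to the
# target R_g (5% band), retrying over derived seeds
grow_coil <- function(n, target, r0, seed, dmin = 0.32) {
  walk <- function(g, sd) {
    set.seed(sd)
    x <- matrix(0, n, 3)
    dir <- c(0, 0, 1)
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:60) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        nd <- g * dir + (1 - g) * u
        nd <- nd / sqrt(sum(nd^2))
        cand <- x[i - 1, ] + nd * r0
        prev <- x[seq_len(max(1, i - 2)), , drop = FALSE]
        if (i <= 2 || min(rowSums(sweep(prev, 2, cand)^2)) > dmin^2) {
          x[i, ] <- cand; dir <- nd; placed <- TRUE; break
        }
      }
      if (!placed) return(NULL)
    }
    x
  }
  # keep the coil globally isotropic (box-sized); relax the extent bound
  # progressively if a seed family cannot satisfy it
  for (ext_factor in c(2.6, 2.9, 3.4, Inf)) {
    max_ext <- ext_factor * target
    for (k in 0:29) {
      sd <- derive_seed(seed, 11L, k)
      lo <- -0.6; hi <- 0.97
      for (it in 1:40) {
        g <- (lo + hi) / 2
        x <- walk(g, sd)
        if (is.null(x)) { lo <- lo + 0.05; next }
        rg <- cpp_rg(x, seq_len(n))
        if (abs(rg - target) <= 0.05 * target &&
            max(stats::dist(x)) <= max_ext) return(x)
        if (rg < target) lo <- g else hi <- g
        if (hi - lo < 1e-4) break
      }
    }
  }
  stop("coil generation failed to reach the target R_g")
}

# greedy compact growth: each bead steps bond-length r0 from the last, picking
# the candidate direction closest to the running centroid subject to a
# minimum site distance; the spacing floor is tuned to the target R_g
grow_globule <- function(n, target, r0, seed) {
  grow <- function(dmin, sd) {
    set.seed(sd)
    x <- matrix(0, n, 3)
    for (i in 2:n) {
      ctr <- colMeans(x[seq_len(i - 1), , drop = FALSE])
      best <- NULL; bestd <- Inf
      for (try in 1:120) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- x[i - 1, ] + u * r0
        prev <- x[seq_len(max(1, i - 2)), , drop = FALSE]
        if (i > 2 && min(rowSums(sweep(prev, 2, cand)^2)) < dmin^2) next
        d <- sum((cand - ctr)^2)
        if (d < bestd) { bestd <- d; best <- cand }
      }
      if (is.null(best)) return(NULL)
      x[i, ] <- best
    }
    x
  }
  for (k in 0:24) {
    sd <- derive_seed(seed, 13L, k)
    lo <- 0.26; hi <- min(1.6 * target, 0.55)
    for (it in 1:40) {
      dmin <- (lo + hi) / 2
      x <- grow(dmin, sd)
      if (is.null(x)) { hi <- dmin; next }
      rg <- cpp_rg(x, seq_len(n))
      if (abs(rg - target) <= 0.05 * target) return(x)
      if (rg < target) lo <- dmin else hi <- dmin
      if (hi - lo < 1e-4) break
    }
  }
  stop("globule generation failed to reach the target R_g")
}
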