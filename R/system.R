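#' Construct a particle system
#'
#' Holds positions (stored unwrapped; the minimum-image convention is applied
#' per pair at evaluation time), velocities, an orthorhombic periodic box,
#' per-particle species indices into a species table, bonded topology and
#' molecule labels.
#'
#' @param positions N x 3 matrix (nm).
#' @param box Edge lengths, length-3 or scalar (nm).
#' @param species_id Integer vector, row index into `species_tbl`.
#' @param species_tbl Species tibble (see [species()]); its row order must
#'   match the force field built from it.
#' @param velocities N x 3 matrix (nm/ps), defaults to zero.
#' @param bonds Matrix with columns (i, j, r0, k) or NULL.
#' @param angles Matrix with columns (i, j, k, theta0, k_theta) with j the
#'   central particle, or NULL.
#' @param mol_id Per-particle molecule index (defaults to one particle per
#'   molecule).
#' @param step Step counter.
#' @return An `md_system` object.
#' @export
md_system <- function(positions, box, species_id, species_tbl,
                      velocities = NULL, bonds = NULL, angles = NULL,
                      mol_id = NULL, step = 0L) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  n <- nrow(positions)
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(box) == 3, all(box > 0))
  species_id <- as.integer(species_id)
  stopifnot(length(species_id) == n,
            all(species_id >= 1), all(species_id <= nrow(species_tbl)))
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  stopifnot(nrow(velocities) == n)
  if (is.null(bonds)) bonds <- matrix(0, 0, 4)
  if (is.null(angles)) angles <- matrix(0, 0, 5)
  if (is.null(mol_id)) {
    # bonded particles share a molecule
    mol_id <- seq_len(n)
    if (nrow(bonds) > 0) {
      for (b in seq_len(nrow(bonds))) {
        i <- bonds[b, 1]; j <- bonds[b, 2]
        m <- min(mol_id[i], mol_id[j])
        mol_id[mol_id == mol_id[i] | mol_id == mol_id[j]] <- m
      }
    }
    mol_id <- match(mol_id, sort(unique(mol_id)))
  }
  role_codes <- c(polymer = 0L, water = 1L, alcohol = 2L)
  mol_role <- vapply(split(seq_len(n), mol_id), function(idx)
    role_codes[[species_tbl$role[species_id[idx[1]]]]], integer(1))
  structure(list(x = positions, v = velocities, box = as.numeric(box),
                 sp = species_id, species = tibble::as_tibble(species_tbl),
                 bonds = bonds, angles = angles,
                 excl = topology_exclusions(bonds, angles),
                 mol_id = as.integer(mol_id), mol_role = as.integer(mol_role),
                 step = as.integer(step)),
            class = "md_system")
}

#' @export
print.md_system <- function(x, ...) {
  cat("<md_system> ", nrow(x$x), " particles, box ",
      paste(signif(x$box, 4), collapse = " x "), " nm, step ", x$step, "\n",
      sep = "")
  invisible(x)
}

# 1-2 and 1-3 nonbonded exclusions from the bonded topology
topology_exclusions <- function(bonds, angles) {
  ex <- NULL
  if (nrow(bonds) > 0) ex <- rbind(ex, bonds[, 1:2, drop = FALSE])
  if (nrow(angles) > 0) ex <- rbind(ex, angles[, c(1, 3), drop = FALSE])
  if (is.null(ex)) matrix(0L, 0, 2) else {
    storage.mode(ex) <- "integer"
    unique(t(apply(ex, 1, sort)))
  }
}

#' Harmonic bead-spring polymer topology
#'
#' Harmonic bonds and angles for a linear chain. The shipped force constants
#' and geometry (r0 = 0.4 nm tangent beads, theta0 = 180 degrees, soft angular
#' stiffness) are configurable defaults of this package, not literature
#' values for the original bead model, whose bonded constants are not
#' published alongside the nonbonded ones.
#'
#' @param n_beads Number of beads.
#' @param r0 Equilibrium bond length (nm).
#' @param k_bond Bond force constant (kJ/mol/nm^2).
#' @param theta0 Equilibrium angle (radians).
#' @param k_angle Angle force constant (kJ/mol/rad^2).
#' @return List with `bonds` and `angles` matrices.
#' @export
polymer_topology <- function(n_beads, r0 = 0.4, k_bond = 10000,
                             theta0 = pi, k_angle = 5) {
  stopifnot(n_beads >= 2)
  i <- seq_len(n_beads - 1)
  bonds <- cbind(i, i + 1, r0, k_bond)
  angles <- if (n_beads >= 3) {
    j <- seq_len(n_beads - 2)
    cbind(j, j + 1, j + 2, theta0, k_angle)
  } else matrix(0, 0, 5)
  list(bonds = bonds, angles = angles)
}

#' Radius of gyration
#'
#' Equal-mass radius of gyration of a selection. If `bonds` and `box` are
#' supplied, the molecule-integrity guard errors when any bond is longer than
#' half the smallest box edge (a broken molecule under the minimum image).
#'
#' @param x N x 3 positions or an `md_system`.
#' @param selection Particle indices (default: all rows / all polymer beads).
#' @param box,bonds Optional periodic box and bond list for the integrity
#'   guard.
#' @return R_g in nm.
#' @export
compute_rg <- function(x, selection = NULL, box = NULL, bonds = NULL) {
  if (inherits(x, "md_system")) {
    if (is.null(selection)) selection <- polymer_selection(x)
    if (is.null(box)) box <- x$box
    if (is.null(bonds)) bonds <- x$bonds
    x <- x$x
  }
  if (is.null(selection)) selection <- seq_len(nrow(x))
  if (length(selection) < 2) stop("need at least 2 selected particles")
  if (!is.null(bonds) && nrow(bonds) > 0 && !is.null(box)) {
    d <- sqrt(rowSums((x[bonds[, 1], , drop = FALSE] -
                         x[bonds[, 2], , drop = FALSE])^2))
    if (any(d > min(box) / 2))
      stop("broken molecule: a bond exceeds half the box; unwrap first")
  }
  cpp_rg(x, as.integer(selection))
}

#' Selection of polymer beads in a system
#' @param sys An `md_system`.
#' @return Integer indices of polymer-role particles.
#' @export
polymer_selection <- function(sys) {
  which(sys$species$role[sys$sp] == "polymer")
}

#' Harmonic restraint on the radius of gyration
#'
#' `V(Rg) = k_b/2 (Rg - rg0)^2`, the umbrella-window bias.
#'
#' @param rg0 Target R_g (nm).
#' @param k_b Force constant (kJ/mol/nm^2), default 20000.
#' @param selection Polymer particle indices.
#' @export
rg_restraint <- function(rg0, k_b = 20000, selection) {
  stopifnot(k_b >= 0, length(selection) >= 1)
  structure(list(rg0 = rg0, k_b = k_b, selection = as.integer(selection)),
            class = "rg_restraint")
}

#' Harmonic position restraint
#'
#' @param reference Reference positions (length(selection) x 3).
#' @param k_pr Force constant (kJ/mol/nm^2), default 1e5.
#' @param selection Restrained particle indices.
#' @export
position_restraint <- function(reference, k_pr = 1e5, selection) {
  reference <- as.matrix(reference)
  stopifnot(k_pr >= 0, nrow(reference) == length(selection))
  structure(list(reference = reference, k_pr = k_pr,
                 selection = as.integer(selection)),
            class = "position_restraint")
}

#' Energy and forces of the R_g restraint alone
#'
#' @param x N x 3 positions.
#' @param restraint An [rg_restraint()].
#' @return List with `rg`, `energy`, `forces`.
#' @export
rg_restraint_energy_forces <- function(x, restraint) {
  x <- as.matrix(x)
  dummy_sig <- matrix(1.0, 1, 1); dummy_eps <- matrix(0.0, 1, 1)
  dummy_mode <- matrix(3L, 1, 1)
  out <- cpp_energy_forces(x, rep(1e6, 3), rep(0L, nrow(x)),
                           dummy_sig, dummy_eps, dummy_mode, 1.0, 1.0,
                           0.5, 1L, 0.3, matrix(0, 0, 4), matrix(0, 0, 5),
                           matrix(0L, 0, 2), restraint$selection,
                           restraint$k_b, restraint$rg0, integer(0),
                           matrix(0, 0, 3), 0.0, 0L)
  list(rg = out$rg, energy = unname(out$energy[["rg_restraint"]]),
       forces = out$forces)
}

# split a restraint list into the arguments of the compiled core
restraint_args <- function(restraints) {
  rg_sel <- integer(0); rg_kb <- 0.0; rg0 <- 0.0
  pr_sel <- integer(0); pr_ref <- matrix(0, 0, 3); kpr <- 0.0
  for (r in restraints) {
    if (inherits(r, "rg_restraint")) {
      rg_sel <- r$selection; rg_kb <- r$k_b; rg0 <- r$rg0
    } else if (inherits(r, "position_restraint")) {
      pr_sel <- r$selection; pr_ref <- r$reference; kpr <- r$k_pr
    } else stop("unknown restraint type")
  }
  list(rg_sel = rg_sel, rg_kb = rg_kb, rg0 = rg0,
       pr_sel = pr_sel, pr_ref = pr_ref, kpr = kpr)
}

# the LJ cutoff may not exceed half the smallest box edge (minimum image)
effective_cutoff <- function(ff, box) min(ff$cutoff, 0.4999 * min(box))

#' Total potential energy and forces
#'
#' Pair terms (minimum image, cell list when the box admits one), bonded
#' terms and restraints, with a per-term energy decomposition and the
#' soft-core dU/dlambda accumulator.
#'
#' @param sys An `md_system`.
#' @param ff A `forcefield`.
#' @param restraints List of [rg_restraint()] / [position_restraint()].
#' @param neighbor_mode -1 auto, 0 all-pairs, 1 cell list.
#' @return List with `energy` (named vector), `forces`, `dudl`, `virial`,
#'   `rg`.
#' @export
total_energy_forces <- function(sys, ff, restraints = list(),
                                neighbor_mode = -1L) {
  ra <- restraint_args(restraints)
  rsel <- if (length(ra$rg_sel)) ra$rg_sel else {
    ps <- polymer_selection(sys)
    if (length(ps) >= 2) ps else integer(0)
  }
  out <- cpp_energy_forces(sys$x, sys$box, sys$sp - 1L, ff$sigma_ij,
                           ff$eps_ij, ff$mode_ij,
                           effective_cutoff(ff, sys$box), ff$lambda,
                           ff$softcore$alpha, ff$softcore$p,
                           ff$softcore$sigma_sc, sys$bonds, sys$angles,
                           sys$excl, rsel, ra$rg_kb, ra$rg0, ra$pr_sel,
                           ra$pr_ref, ra$kpr, as.integer(neighbor_mode))
  out
}

#' Integrator settings
#'
#' BAOAB discretisation of Langevin dynamics. `friction_time` is the inverse
#' friction constant (ps); `friction_time = Inf` recovers deterministic
#' velocity-Verlet dynamics.
#'
#' @param dt Time step (ps), default 0.002.
#' @param temperature Temperature (K), default 300.
#' @param friction_time Inverse friction constant (ps), default 0.1.
#' @param barostat `NULL` or an [mc_barostat()].
#' @export
integrator_spec <- function(dt = 0.002, temperature = 300,
                            friction_time = 0.1, barostat = NULL) {
  stopifnot(dt > 0, friction_time > 0, temperature >= 0)
  structure(list(dt = dt, temperature = temperature,
                 friction_time = friction_time, barostat = barostat),
            class = "integrator_spec")
}

#' Monte Carlo volume barostat
#'
#' Isotropic ln-V moves with molecular centre-of-mass scaling, used to
#' pre-equilibrate solvent densities at a target pressure.
#'
#' @param pressure Target pressure (kJ/mol/nm^3); `pressure_atm(1)` is 1 atm.
#' @param interval Steps between volume moves.
#' @param max_dlnV Maximum ln-V displacement.
#' @export
mc_barostat <- function(pressure = pressure_atm(1), interval = 25L,
                        max_dlnV = 0.02) {
  structure(list(pressure = pressure, interval = as.integer(interval),
                 max_dlnV = max_dlnV), class = "mc_barostat")
}

#' Convert atmospheres to kJ/mol/nm^3
#' @param p Pressure in atm.
#' @export
pressure_atm <- function(p) p * PRESSURE_ATM

#' Draw Maxwell-Boltzmann velocities
#'
#' @param sys An `md_system`.
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @return The system with fresh velocities.
#' @export
maxwell_velocities <- function(sys, temperature = 300, seed = 1L) {
  set.seed(seed)
  m <- sys$species$mass[sys$sp]
  sd <- sqrt(GAS_CONSTANT * temperature / m)
  sys$v <- matrix(rnorm(3 * nrow(sys$x)), ncol = 3) * sd
  sys
}

#' Advance the system by one Langevin step
#'
#' Single BAOAB update; identical to [run_segment()] with `n_steps = 1`.
#'
#' @inheritParams run_segment
#' @return The updated `md_system`.
#' @export
langevin_step <- function(sys, ff, spec = integrator_spec(),
                          restraints = list(), seed = 1L) {
  run_segment(sys, ff, spec, n_steps = 1L, restraints = restraints,
              seed = seed, stride = 0L)$system
}

#' Propagate the system and record observables
#'
#' Runs `n_steps` of BAOAB Langevin dynamics, sampling the radius of
#' gyration, the energy decomposition, dU/dlambda, the virial and (when
#' `shell_cutoff > 0`) first-solvation-shell molecule counts every `stride`
#' steps. Deterministic for a fixed seed.
#'
#' @param sys An `md_system`.
#' @param ff A `forcefield`.
#' @param spec An [integrator_spec()].
#' @param n_steps Number of steps.
#' @param restraints Restraint list.
#' @param seed Integer seed for the thermostat stream.
#' @param stride Sampling stride (0 = no records).
#' @param shell_cutoff First-shell distance cutoff (nm); 0 disables shell
#'   counting.
#' @param neighbor_mode -1 auto, 0 all-pairs, 1 cell list.
#' @return List with the advanced `system` and a `records` tibble.
#' @export
run_segment <- function(sys, ff, spec = integrator_spec(), n_steps,
                        restraints = list(), seed = 1L, stride = 10L,
                        shell_cutoff = 0, neighbor_mode = -1L) {
  ra <- restraint_args(restraints)
  rsel <- if (length(ra$rg_sel)) ra$rg_sel else {
    ps <- polymer_selection(sys)
    if (length(ps) >= 2) ps else integer(0)
  }
  baro <- spec$barostat
  out <- cpp_run_segment(sys$x, sys$v, sys$box, sys$sp - 1L,
                         sys$species$mass[sys$sp], ff$sigma_ij, ff$eps_ij,
                         ff$mode_ij, effective_cutoff(ff, sys$box),
                         ff$lambda, ff$softcore$alpha, ff$softcore$p,
                         ff$softcore$sigma_sc, sys$bonds, sys$angles,
                         sys$excl, rsel, ra$rg_kb, ra$rg0, ra$pr_sel,
                         ra$pr_ref, ra$kpr, as.integer(neighbor_mode),
                         as.integer(n_steps), spec$dt, spec$temperature,
                         spec$friction_time, as.integer(seed),
                         as.integer(stride),
                         if (is.null(baro)) 0L else baro$interval,
                         if (is.null(baro)) 0 else baro$pressure,
                         if (is.null(baro)) 0 else baro$max_dlnV,
                         sys$mol_id, sys$mol_role, shell_cutoff, sys$step)
  sys$x <- out$x; sys$v <- out$v; sys$box <- out$box; sys$step <- out$step
  rec <- tibble::as_tibble(out$records)
  attr(rec, "baro_acceptance") <-
    if (out$baro_tried > 0) out$baro_accepted / out$baro_tried else NA_real_
  list(system = sys, records = rec)
}

#' Steepest-descent energy minimisation
#'
#' @param sys An `md_system`.
#' @param ff A `forcefield`.
#' @param restraints Restraint list.
#' @param max_steps Iteration cap.
#' @param ftol Convergence threshold on the max force component (kJ/mol/nm).
#' @param step0 Initial displacement of the largest force component (nm).
#' @return List with the minimised `system`, final `energy`, `fmax`,
#'   `iterations`.
#' @export
minimize <- function(sys, ff, restraints = list(), max_steps = 1000,
                     ftol = 10, step0 = 0.01) {
  ra <- restraint_args(restraints)
  rsel <- if (length(ra$rg_sel)) ra$rg_sel else integer(0)
  out <- cpp_minimize(sys$x, sys$box, sys$sp - 1L, ff$sigma_ij, ff$eps_ij,
                      ff$mode_ij, effective_cutoff(ff, sys$box), ff$lambda,
                      ff$softcore$alpha, ff$softcore$p, ff$softcore$sigma_sc,
                      sys$bonds, sys$angles, sys$excl, rsel, ra$rg_kb,
                      ra$rg0, ra$pr_sel, ra$pr_ref, ra$kpr, -1L,
                      as.integer(max_steps), ftol, step0)
  sys$x <- out$x
  list(system = sys, energy = out$energy, fmax = out$fmax,
       iterations = out$iterations)
}

#' Virial-route pressure from a records tibble
#'
#' `P = (N kT + <virial>/3) / V` with the pair virial `sum r.f` sampled
#' during [run_segment()].
#'
#' @param records Records tibble from [run_segment()].
#' @param n_particles Number of particles.
#' @param temperature Temperature (K).
#' @return Mean pressure (kJ/mol/nm^3).
#' @export
virial_pressure <- function(records, n_particles, temperature = 300) {
  mean((n_particles * GAS_CONSTANT * temperature +
          records$virial / 3) / records$volume)
}
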