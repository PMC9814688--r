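#' Coupling schedule for thermodynamic integration
#'
#' The production protocol uses 21 evenly spaced values (spacing 0.05).
#' `power > 1` clusters points near lambda = 0, where the soft-core
#' dU/dlambda of a ghost cavity decays steeply as solvent is expelled;
#' a quadratic schedule resolves that boundary layer at desk scale with
#' far fewer points than a uniform grid.
#'
#' @param n Number of lambda points; the default 21 gives spacing 0.05.
#' @param power Exponent of the grid map `(k/(n-1))^power` (default 1,
#'   uniform).
#' @param values Explicit values (must start at 0, end at 1, strictly
#'   increasing); overrides `n` and `power`.
#' @export
lambda_schedule <- function(n = 21, power = 1, values = NULL) {
  if (is.null(values)) values <- (seq(0, 1, length.out = n))^power
  stopifnot(values[1] == 0, values[length(values)] == 1,
            all(diff(values) > 0))
  values
}

#' Prepare a fixed-conformation cavity system
#'
#' Embeds the polymer snapshot in a solvent mixture, freezes it with a stiff
#' position restraint on every bead (default 1e5 kJ/mol/nm^2), sets all
#' polymer-(co)solvent pairs to soft-core WCA and minimises. At lambda = 0
#' the restrained polymer is a ghost (the cavity-free binary solvent); at
#' lambda = 1 the full repulsive cavity is present. Intramolecular polymer
#' interactions are retained at all lambda (they are lambda-independent and
#' cancel in differences).
#'
#' @param conformation `md_system` polymer snapshot (see [make_conformers()]).
#' @param spec A [reduced_solvent_spec()].
#' @param x_alcohol Cosolvent mole fraction.
#' @param n_solvent Solvent molecules.
#' @param k_pr Position-restraint force constant (kJ/mol/nm^2).
#' @param seed Integer seed.
#' @param box Optional box edge (nm).
#' @param minimize_steps Steepest-descent steps after packing.
#' @return List with `system`, `ff` (soft-core polymer-solvent modes),
#'   `restraints`, `x_alcohol`.
#' @export
prepare_cavity_system <- function(conformation, spec, x_alcohol, n_solvent,
                                  k_pr = 1e5, seed = 1L, box = NULL,
                                  minimize_steps = 300) {
  sys <- build_mixture(spec, x_alcohol, n_solvent, seed = seed, box = box,
                       polymer = conformation)
  ff <- mixture_forcefield(spec)
  ff <- set_pair_mode(ff, "polymer", "water", "softcore")
  ff <- set_pair_mode(ff, "polymer", "alcohol", "softcore")
  sel <- polymer_selection(sys)
  restraints <- list(position_restraint(sys$x[sel, , drop = FALSE],
                                        k_pr = k_pr, selection = sel))
  if (minimize_steps > 0 && n_solvent > 0) {
    ff1 <- set_lambda(ff, 1)
    sys <- minimize(sys, ff1, restraints, max_steps = minimize_steps,
                    ftol = 50)$system
  }
  list(system = sys, ff = ff, restraints = restraints,
       x_alcohol = x_alcohol)
}

#' Sample dU/dlambda at one coupling value
#'
#' Minimises, equilibrates, then averages the soft-core dU/dlambda over a
#' production run; the standard error comes from block averaging.
#'
#' @param prepared Output of [prepare_cavity_system()] (or a compatible
#'   list with `system`, `ff`, `restraints`).
#' @param lam Coupling value in \[0, 1\].
#' @param spec An [integrator_spec()].
#' @param n_equil,n_prod Equilibration / production steps.
#' @param stride Sampling stride.
#' @param seed Integer seed.
#' @param n_blocks Blocks for the standard error.
#' @param minimize_steps Steepest-descent steps before equilibration.
#' @return List with `dudl_mean`, `dudl_stderr`, `n_samples`, `records`.
#' @export
sample_dudl <- function(prepared, lam, spec = integrator_spec(),
                        n_equil = 1000, n_prod = 5000, stride = 10L,
                        seed = 1L, n_blocks = 5, minimize_steps = 100) {
  ff <- set_lambda(prepared$ff, lam)
  sys <- prepared$system
  if (minimize_steps > 0)
    sys <- minimize(sys, ff, prepared$restraints,
                    max_steps = minimize_steps, ftol = 100)$system
  sys <- maxwell_velocities(sys, spec$temperature, derive_seed(seed, 4L))
  if (n_equil > 0)
    sys <- run_segment(sys, ff, spec, n_equil, prepared$restraints,
                       seed = derive_seed(seed, 5L), stride = 0L)$system
  out <- run_segment(sys, ff, spec, n_prod, prepared$restraints,
                     seed = derive_seed(seed, 6L), stride = stride)
  d <- out$records$dudl
  blk <- split(d, cut(seq_along(d), n_blocks, labels = FALSE))
  bm <- vapply(blk, mean, numeric(1))
  list(dudl_mean = mean(d), dudl_stderr = stats::sd(bm) / sqrt(length(bm)),
       n_samples = length(d), records = out$records, system = out$system)
}

#' Integrate a dU/dlambda series over lambda
#'
#' Trapezoidal quadrature (the 21 evenly spaced points of the production
#' protocol make the trapezoid exact for linear dU/dlambda); the error is
#' the square root of the weight-squared sum of per-point variances.
#'
#' @param lambdas Lambda values.
#' @param dudl_mean Mean dU/dlambda per point.
#' @param dudl_stderr Standard errors per point.
#' @param conformation Tag (`"coil"`, `"globule"`, ...).
#' @param x_alcohol Composition tag.
#' @return A `ti_result`: tibble of the series with attributes `dg`,
#'   `dg_stderr`.
#' @export
integrate_ti <- function(lambdas, dudl_mean, dudl_stderr = NA_real_,
                         conformation = NA_character_,
                         x_alcohol = NA_real_) {
  stopifnot(length(lambdas) == length(dudl_mean), all(diff(lambdas) > 0))
  n <- length(lambdas)
  h <- diff(lambdas)
  wts <- c(h / 2, 0) + c(0, h / 2)
  dg <- sum(wts * dudl_mean)
  dg_se <- if (all(is.finite(dudl_stderr)))
    sqrt(sum(wts^2 * dudl_stderr^2)) else NA_real_
  out <- tibble::tibble(lambda = lambdas, dudl = dudl_mean,
                        dudl_stderr = dudl_stderr)
  structure(out, class = c("ti_result", class(out)), dg = dg,
            dg_stderr = dg_se, conformation = conformation,
            x_alcohol = x_alcohol)
}

#' Cavity work of one conformation at one composition
#'
#' Full TI sweep. Lambda points are chained: each coupling value starts from
#' the final configuration of the previous one (after an extended
#' equilibration of the first point), which is how slowly relaxing solvent
#' structure around the large cavity is carried along the schedule.
#'
#' @inheritParams sample_dudl
#' @param schedule Lambda values from [lambda_schedule()].
#' @param conformation Tag stored in the result.
#' @param n_preequil Extra equilibration steps before the first lambda.
#' @return A `ti_result`.
#' @export
ti_run <- function(prepared, schedule = lambda_schedule(),
                   spec = integrator_spec(), n_equil = 1000, n_prod = 5000,
                   stride = 10L, seed = 1L, conformation = NA_character_,
                   minimize_steps = 100, n_preequil = 4 * n_equil) {
  # decouple downward: start from the fully coupled (packed, overlap-free)
  # cavity and soften it, so solvent enters the opening cavity reversibly
  # instead of having to be squeezed out of the solute interior; points
  # with lambda < 0.1 relax longer because the ghost region must refill by
  # diffusion
  ord <- rev(seq_along(schedule))
  res <- vector("list", length(schedule))
  first <- TRUE
  for (i in ord) {
    extra <- if (schedule[i] < 0.1) 3L else 1L
    res[[i]] <- sample_dudl(prepared, schedule[i], spec,
                            if (first) n_equil + n_preequil
                            else extra * n_equil,
                            n_prod, stride, seed = derive_seed(seed, 7L, i),
                            minimize_steps = if (first) minimize_steps else 0)
    prepared$system <- res[[i]]$system
    first <- FALSE
  }
  integrate_ti(schedule, vapply(res, `[[`, numeric(1), "dudl_mean"),
               vapply(res, `[[`, numeric(1), "dudl_stderr"),
               conformation = conformation,
               x_alcohol = prepared$x_alcohol)
}

#' Excluded-volume collapse free-energy difference
#'
#' `ddG = dG_globule - dG_coil`; negative values mean the smaller (globule)
#' cavity is cheaper to create, which holds whenever the globule exposes
#' less surface. Warns if the sign comes out positive.
#'
#' @param coil,globule `ti_result` objects.
#' @return List with `ddg` and `stderr`.
#' @export
excl_vol_difference <- function(coil, globule) {
  ddg <- attr(globule, "dg") - attr(coil, "dg")
  se <- sqrt(sum(c(attr(globule, "dg_stderr"), attr(coil, "dg_stderr"))^2))
  if (is.finite(ddg) && ddg > 0)
    warning("ddG_excl_vol > 0: the coil cavity appears cheaper than the globule cavity")
  list(ddg = ddg, stderr = se)
}

#' TI campaign over a composition grid
#'
#' For each composition, runs the cavity TI for fixed coil and globule
#' snapshots with independent derived seeds and reports the cavity-work
#' curves and their difference, plus the location of the interior minimum of
#' the difference. Boxes are sized per conformation (spatial extent plus
#' `clearance` on each side) and solvent counts per composition are derived
#' from the model's liquid molar volumes, so every system is a bulk liquid
#' around an image-separated solute.
#'
#' @param coil,globule Polymer snapshots (see [make_conformers()]).
#' @param spec_solvent A [reduced_solvent_spec()].
#' @param x_grid Compositions.
#' @param n_solvent Solvent molecules per system; `NULL` (default) derives
#'   the count per composition from the box volume.
#' @param clearance Solvent clearance around the solute (nm) when sizing
#'   boxes automatically.
#' @param cutoff LJ cutoff used for the campaign (nm).
#' @param schedule Lambda schedule.
#' @param spec An [integrator_spec()].
#' @param n_equil,n_prod Steps per lambda.
#' @param n_preequil Extra equilibration before the first (fully coupled)
#'   lambda point; long enough for cosolvent to diffuse to the cavity
#'   surface.
#' @param stride Sampling stride.
#' @param common_box Solvate both conformations in the same (coil-sized)
#'   box so they see identical solvent reservoirs (default TRUE; at small
#'   reservoirs preferential adsorption otherwise depletes the two systems
#'   differently).
#' @param seed Master seed.
#' @param k_pr Position-restraint constant.
#' @return List with `table` (tibble: x_alcohol, conformation, dg, stderr),
#'   `ddg` (tibble: x_alcohol, ddg, stderr), `x_c_min`, `results` (nested
#'   `ti_result`s).
#' @export
ti_campaign <- function(coil, globule, spec_solvent, x_grid, n_solvent = NULL,
                        clearance = 0.35, cutoff = 1.0,
                        schedule = lambda_schedule(13, power = 2),
                        spec = integrator_spec(barostat = mc_barostat()),
                        n_equil = 300, n_prod = 1500, stride = 8L,
                        n_preequil = 4000L, common_box = TRUE, seed = 1L,
                        k_pr = 1e5) {
  confs <- list(coil = coil, globule = globule)
  boxes <- lapply(confs, conformer_box, clearance = clearance)
  if (common_box) boxes$globule <- boxes$coil
  results <- list()
  rows <- list(); drows <- list()
  for (ix in seq_along(x_grid)) {
    x <- x_grid[ix]
    for (cn in names(confs)) {
      bx <- boxes[[cn]]
      ns <- if (is.null(n_solvent))
        solvent_count_for_box(spec_solvent, x, bx, nrow(confs[[cn]]$x))
      else n_solvent
      prep <- prepare_cavity_system(confs[[cn]], spec_solvent, x, ns,
                                    k_pr = k_pr, box = bx,
                                    seed = derive_seed(seed, 8L,
                                                       ix * 10 + match(cn, names(confs))))
      prep$ff$cutoff <- cutoff
      r <- ti_run(prep, schedule, spec, n_equil, n_prod, stride,
                  seed = derive_seed(seed, 9L, ix * 10 + match(cn, names(confs))),
                  conformation = cn, n_preequil = n_preequil)
      results[[paste0(cn, "_", x)]] <- r
      rows[[length(rows) + 1]] <- tibble::tibble(
        x_alcohol = x, conformation = cn, dg = attr(r, "dg"),
        stderr = attr(r, "dg_stderr"))
    }
    dd <- excl_vol_difference(results[[paste0("coil_", x)]],
                              results[[paste0("globule_", x)]])
    drows[[length(drows) + 1]] <- tibble::tibble(
      x_alcohol = x, ddg = dd$ddg, stderr = dd$stderr)
  }
  tab <- dplyr::bind_rows(rows)
  ddg <- dplyr::bind_rows(drows)
  im <- which.min(ddg$ddg)
  x_c_min <- if (length(im) == 1 && im > 1 && im < nrow(ddg))
    ddg$x_alcohol[im] else NA_real_
  list(table = tab, ddg = ddg, x_c_min = x_c_min, results = results)
}
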