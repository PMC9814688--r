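#' Shrake-Rupley solvent-accessible surface area
#'
#' Golden-spiral quadrature: points on each probe-expanded sphere that are
#' not buried inside any other expanded sphere count toward that particle's
#' accessible area.
#'
#' @param positions N x 3 coordinates (nm) or an `md_system` (polymer beads
#'   are used).
#' @param radii Per-particle radii (nm); by default sigma/2 of the species.
#' @param probe Probe radius (nm), default 0.14.
#' @param n_points Quadrature points per sphere (>= 16), default 960.
#' @return A `sasa_result`: list with `total`, `per_particle`, `probe`,
#'   `n_points`.
#' @export
shrake_rupley_sasa <- function(positions, radii = NULL, probe = 0.14,
                               n_points = 960) {
  if (n_points < 16) stop("n_points < 16 gives a meaningless quadrature")
  if (inherits(positions, "md_system")) {
    sel <- polymer_selection(positions)
    if (is.null(radii)) radii <- positions$species$sigma[positions$sp[sel]] / 2
    positions <- positions$x[sel, , drop = FALSE]
  }
  positions <- as.matrix(positions)
  if (is.null(radii)) stop("radii required for bare coordinate input")
  if (length(radii) == 1) radii <- rep(radii, nrow(positions))
  stopifnot(all(radii > 0), length(radii) == nrow(positions))
  out <- cpp_sasa(positions, radii, probe, as.integer(n_points))
  structure(list(total = out$total, per_particle = out$per_particle,
                 probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> total ", signif(x$total, 5), " nm^2 over ",
      length(x$per_particle), " particles (probe ", x$probe, " nm)\n",
      sep = "")
  invisible(x)
}

#' Count first-shell solvent molecules around the polymer
#'
#' A solvent molecule is in the first shell when any of its sites lies
#' within `shell_cutoff` (minimum image) of any polymer bead.
#'
#' @param sys An `md_system`.
#' @param shell_cutoff Shell cutoff (nm).
#' @param selection Polymer bead indices (default: polymer role).
#' @return Named integer vector `(n_water, n_alcohol, n_water_bulk,
#'   n_alcohol_bulk)`.
#' @export
first_shell_counts <- function(sys, shell_cutoff, selection = NULL) {
  if (is.null(selection)) selection <- polymer_selection(sys)
  out <- cpp_shell_counts(sys$x, sys$box, as.integer(selection), sys$mol_id,
                          sys$mol_role, shell_cutoff)
  stats::setNames(as.integer(out),
                  c("n_water", "n_alcohol", "n_water_bulk", "n_alcohol_bulk"))
}

#' Preferential binding coefficient from shell-count records
#'
#' `Gamma = <n_a>_shell - (N_a^bulk / N_w^bulk) <n_w>_shell`, evaluated per
#' frame with the bulk counts taken outside the shell, then averaged; the
#' standard error comes from block averaging.
#'
#' @param records Records tibble with `na_shell`, `nw_shell`, `na_bulk`,
#'   `nw_bulk` columns (from [run_segment()] with `shell_cutoff > 0`), or a
#'   data frame with those columns.
#' @param n_blocks Blocks for the standard error.
#' @return List with `gamma`, `stderr`, `n_frames`, and the mean shell
#'   counts.
#' @export
preferential_binding <- function(records, n_blocks = 5) {
  stopifnot(all(c("na_shell", "nw_shell", "na_bulk", "nw_bulk") %in%
                  names(records)))
  g <- records$na_shell -
    ifelse(records$nw_bulk > 0, records$na_bulk / records$nw_bulk, 0) *
      records$nw_shell
  blk <- split(g, cut(seq_along(g), n_blocks, labels = FALSE))
  bm <- vapply(blk, mean, numeric(1))
  list(gamma = mean(g), stderr = stats::sd(bm) / sqrt(length(bm)),
       n_frames = length(g), mean_shell_water = mean(records$nw_shell),
       mean_shell_alcohol = mean(records$na_shell))
}

#' Polymer-solvent radial distribution function
#'
#' Minimum-image site-site g(r) between polymer beads and solvent sites,
#' averaged over frames; used to place the first-shell cutoff at the first
#' minimum.
#'
#' @param frames List of `md_system` frames.
#' @param r_max Maximum distance (nm).
#' @param bin Bin width (nm).
#' @return Tibble with `r` and `g`.
#' @export
polymer_solvent_rdf <- function(frames, r_max = 1.2, bin = 0.02) {
  edges <- seq(0, r_max, by = bin)
  acc <- numeric(length(edges) - 1)
  norm <- 0
  for (fr in frames) {
    sel <- polymer_selection(fr)
    sol <- setdiff(seq_len(nrow(fr$x)), sel)
    if (!length(sel) || !length(sol)) next
    d <- NULL
    for (i in sel) {
      dd <- sweep(fr$x[sol, , drop = FALSE], 2, fr$x[i, ])
      dd <- dd - sweep(round(sweep(dd, 2, fr$box, "/")), 2, fr$box, "*")
      d <- c(d, sqrt(rowSums(dd^2)))
    }
    acc <- acc + graphics::hist(d[d < r_max], breaks = edges,
                                plot = FALSE)$counts
    rho <- length(sol) / prod(fr$box)
    norm <- norm + length(sel) * rho
  }
  cent <- (edges[-1] + edges[-length(edges)]) / 2
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  tibble::tibble(r = cent,
                 g = acc / pmax(norm, .Machine$double.eps) / shell_vol)
}

#' First-minimum shell cutoff from an RDF
#'
#' Returns the position of the first local minimum of g(r) after its first
#' peak, or `fallback` when the curve has no resolved minimum.
#'
#' @param rdf Tibble from [polymer_solvent_rdf()].
#' @param fallback Cutoff when no minimum is found (nm).
#' @export
shell_cutoff_from_rdf <- function(rdf, fallback = 0.55) {
  g <- rdf$g; r <- rdf$r
  pk <- which.max(g)
  if (length(g) < pk + 2 || max(g) <= 0) return(fallback)
  after <- seq(pk + 1, length(g) - 1)
  mins <- after[g[after] <= g[after - 1] & g[after] <= g[after + 1]]
  if (length(mins) == 0) fallback else r[mins[1]]
}

#' Saturation concentration of the shell occupancy
#'
#' Fits mean first-shell cosolvent counts versus bulk composition to a
#' Langmuir-type saturating form `n(X) = n_max K X / (1 + K X)` and reports
#' the smallest grid composition where the local slope of the fit falls
#' below 10% of its initial slope. A profile that stays essentially linear
#' (no saturation inside the grid) returns `NA` with a warning.
#'
#' @param profile Tibble with `x_alcohol` and `n_shell` columns (an
#'   adsorption profile).
#' @param slope_frac Slope threshold as a fraction of the initial slope.
#' @return List with `x_sat`, the fitted `n_max`, `K`, and the fit object.
#' @export
saturation_concentration <- function(profile, slope_frac = 0.1) {
  stopifnot(all(c("x_alcohol", "n_shell") %in% names(profile)))
  df <- profile[order(profile$x_alcohol), ]
  df <- df[df$x_alcohol > 0 | df$n_shell == 0, ]
  n0 <- max(df$n_shell)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(n_shell ~ nmax * K * x_alcohol / (1 + K * x_alcohol),
                 data = df, start = list(nmax = n0 * 1.5, K = 5),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("saturation fit failed; profile may be non-saturating")
    return(list(x_sat = NA_real_, n_max = NA_real_, K = NA_real_,
                fit = NULL))
  }
  cf <- coef(fit)
  # slope(X)/slope(0) = 1/(1+KX)^2 ; threshold crossing at X* = (1/sqrt(f)-1)/K
  x_star <- (1 / sqrt(slope_frac) - 1) / cf[["K"]]
  grid <- df$x_alcohol[df$x_alcohol > 0]
  hit <- grid[grid >= x_star]
  if (length(hit) == 0 || cf[["K"]] <= 0) {
    warning("no saturation inside the sampled composition grid")
    return(list(x_sat = NA_real_, n_max = cf[["nmax"]], K = cf[["K"]],
                fit = fit))
  }
  list(x_sat = hit[1], n_max = cf[["nmax"]], K = cf[["K"]], fit = fit)
}

#' SASA scaling exponents of coil and globule conformers
#'
#' Builds extended and collapsed conformers at each chain length and fits
#' log-log least-squares slopes `SASA ~ N^alpha`. The coil exponent exceeds
#' the globule exponent because an extended chain exposes nearly its full
#' surface (alpha -> 1 for a rod) while a compact globule only exposes its
#' boundary (alpha -> 2/3).
#'
#' @param n_list Chain lengths.
#' @param seed Integer seed.
#' @param kinds Conformer kinds for the two branches.
#' @param probe,n_points Passed to [shrake_rupley_sasa()].
#' @return List with `alpha_coil`, `alpha_globule`, `table`.
#' @export
sasa_scaling <- function(n_list = c(16, 32, 64, 128), seed = 1L,
                         kinds = c("coil", "globule"), probe = 0.14,
                         n_points = 480) {
  rows <- list()
  for (kind in kinds) {
    for (n in n_list) {
      conf <- make_conformers(n, kind, seed = derive_seed(seed, 21L, n))
      s <- shrake_rupley_sasa(conf, probe = probe, n_points = n_points)
      rows[[length(rows) + 1]] <- tibble::tibble(kind = kind, n = n,
                                                 sasa = s$total)
    }
  }
  tab <- dplyr::bind_rows(rows)
  slope <- function(k) {
    d <- tab[tab$kind == k, ]
    unname(coef(lm(log(sasa) ~ log(n), data = d))[2])
  }
  list(alpha_coil = slope(kinds[1]), alpha_globule = slope(kinds[2]),
       table = tab)
}

#' Adsorption campaign: first-shell composition vs. bulk composition
#'
#' For each composition and conformation, embeds the frozen (position
#' restrained) polymer with purely repulsive polymer-(co)solvent WCA
#' interactions in the mixture, equilibrates, and records first-shell counts
#' and the preferential binding coefficient. Boxes and solvent counts are
#' sized as in [ti_campaign()].
#'
#' @param coil,globule Polymer snapshots.
#' @param spec_solvent A [reduced_solvent_spec()].
#' @param x_grid Compositions (> 0).
#' @param n_solvent Solvent molecules; `NULL` derives the count per
#'   composition from the box volume.
#' @param clearance Solvent clearance (nm) when sizing boxes.
#' @param cutoff LJ cutoff (nm).
#' @param spec An [integrator_spec()].
#' @param n_equil,n_prod Steps.
#' @param stride Sampling stride.
#' @param shell_cutoff First-shell cutoff (nm); the default 0.55 sits at
#'   the first minimum of the polymer-solvent RDF of the reduced model.
#' @param common_box Solvate both conformations in the same (coil-sized)
#'   box so their binding coefficients see identical reservoirs (default
#'   TRUE, matching the production setup of one system size for all
#'   conformations).
#' @param seed Master seed.
#' @return An `adsorption_profile`: tibble (x_alcohol, conformation,
#'   n_shell_water, n_shell_alcohol, n_shell, gamma, gamma_stderr) with the
#'   shell cutoff as an attribute.
#' @export
adsorption_campaign <- function(coil, globule, spec_solvent, x_grid,
                                n_solvent = NULL, clearance = 0.35,
                                cutoff = 1.0,
                                spec = integrator_spec(barostat = mc_barostat()),
                                n_equil = 1500, n_prod = 4000, stride = 20L,
                                shell_cutoff = 0.55, common_box = TRUE,
                                seed = 1L) {
  confs <- list(coil = coil, globule = globule)
  boxes <- lapply(confs, conformer_box, clearance = clearance)
  if (common_box) boxes$globule <- boxes$coil
  rows <- list()
  for (ix in seq_along(x_grid)) {
    for (cn in names(confs)) {
      bx <- boxes[[cn]]
      ns <- if (is.null(n_solvent))
        solvent_count_for_box(spec_solvent, x_grid[ix], bx,
                              nrow(confs[[cn]]$x))
      else n_solvent
      prep <- prepare_cavity_system(confs[[cn]], spec_solvent, x_grid[ix],
                                    ns, box = bx,
                                    seed = derive_seed(seed, 31L, ix * 10 +
                                                         match(cn, names(confs))))
      prep$ff$cutoff <- cutoff
      ff <- set_lambda(prep$ff, 1) # full WCA cavity
      sys <- maxwell_velocities(prep$system, spec$temperature,
                                derive_seed(seed, 32L, ix))
      sys <- run_segment(sys, ff, spec, n_equil, prep$restraints,
                         seed = derive_seed(seed, 33L, ix * 10 +
                                              match(cn, names(confs))),
                         stride = 0L)$system
      out <- run_segment(sys, ff, spec, n_prod, prep$restraints,
                         seed = derive_seed(seed, 34L, ix * 10 +
                                              match(cn, names(confs))),
                         stride = stride, shell_cutoff = shell_cutoff)
      pb <- preferential_binding(out$records)
      rows[[length(rows) + 1]] <- tibble::tibble(
        x_alcohol = x_grid[ix], conformation = cn,
        n_shell_water = pb$mean_shell_water,
        n_shell_alcohol = pb$mean_shell_alcohol,
        n_shell = pb$mean_shell_alcohol,
        gamma = pb$gamma, gamma_stderr = pb$stderr)
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("adsorption_profile", class(out)),
            shell_cutoff = shell_cutoff)
}
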