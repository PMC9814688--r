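#' Define an interaction species
#'
#' A species is one Lennard-Jones site type: the generic polymer bead, the
#' one-site water-like solvent, or an alcohol-like cosolvent site.
#'
#' @param name Species label.
#' @param sigma LJ diameter (nm).
#' @param epsilon LJ well depth (kJ/mol).
#' @param mass Site mass (amu).
#' @param role One of `"polymer"`, `"water"`, `"alcohol"`.
#' @return A one-row tibble.
#' @examples
#' species("P", 0.4, 1.0, 40, "polymer")
#' @export
species <- function(name, sigma, epsilon, mass, role) {
  role <- match.arg(role, c("polymer", "water", "alcohol"))
  stopifnot(sigma > 0, epsilon >= 0, mass > 0)
  tibble::tibble(name = name, sigma = sigma, epsilon = epsilon,
                 mass = mass, role = role)
}

#' Scaling of polymer-(co)solvent attractions
#'
#' The Lorentz-Berthelot polymer-water and polymer-alcohol well depths are
#' multiplied by `lambda_pw` and `lambda_pa` respectively, with the LJ
#' diameters left unchanged. The defaults reproduce good-solvent conditions
#' for the generic bead polymer at 300 K.
#'
#' @param lambda_pw Polymer-water scaling (default 1.095).
#' @param lambda_pa Polymer-alcohol scaling (default 0.949).
#' @export
lambda_scaling <- function(lambda_pw = 1.095, lambda_pa = 0.949) {
  stopifnot(lambda_pw > 0, lambda_pa > 0)
  structure(list(lambda_pw = lambda_pw, lambda_pa = lambda_pa),
            class = "lambda_scaling")
}

#' Soft-core coupling parameters
#'
#' Beutler-form soft core used during thermodynamic integration to avoid the
#' r -> 0 singularity at small coupling: rsc^6 = alpha sigma_sc^6 (1-lambda)^p + r^6.
#'
#' @param alpha Soft-core alpha (default 0.5).
#' @param p Integer lambda power (default 1).
#' @param sigma_sc Soft-core sigma in nm (default 0.3).
#' @export
softcore_params <- function(alpha = 0.5, p = 1L, sigma_sc = 0.3) {
  stopifnot(alpha >= 0, p >= 1, sigma_sc > 0)
  structure(list(alpha = alpha, p = as.integer(p), sigma_sc = sigma_sc),
            class = "softcore_params")
}

#' Parameters of one interacting pair
#'
#' @param sigma_ij Pair LJ diameter (nm).
#' @param epsilon_ij Pair well depth (kJ/mol).
#' @param mode One of `"LJ"`, `"WCA"`, `"softcore"`, `"excluded"`.
#' @export
pair_params <- function(sigma_ij, epsilon_ij, mode = "LJ") {
  mode <- match.arg(mode, c("LJ", "WCA", "softcore", "excluded"))
  stopifnot(sigma_ij > 0, epsilon_ij >= 0)
  structure(list(sigma_ij = sigma_ij, epsilon_ij = epsilon_ij, mode = mode),
            class = "pair_params")
}

mode_code <- function(mode) {
  match(mode, c("LJ", "WCA", "softcore", "excluded")) - 1L
}

#' Lennard-Jones pair energy and force
#'
#' Plain truncation at `cutoff` without shift; energy and force are zero
#' beyond it.
#'
#' @param r Distances (nm), all > 0.
#' @param pp A [pair_params()] with mode `"LJ"`.
#' @param cutoff Truncation distance (nm), default 1.4.
#' @return A list with `energy` and `force` (the magnitude -dU/dr), both
#'   vectors along `r`.
#' @export
lj_energy_force <- function(r, pp, cutoff = 1.4) {
  stopifnot(inherits(pp, "pair_params"), pp$mode == "LJ")
  if (any(r <= 0)) stop("r must be positive")
  out <- cpp_pair_potential(r, pp$sigma_ij, pp$epsilon_ij, 0L, cutoff,
                            1.0, 0.5, 1L, 0.3)
  list(energy = out$energy, force = out$force)
}

#' WCA pair energy and force
#'
#' The purely repulsive Weeks-Chandler-Andersen part of the LJ potential:
#' LJ + epsilon for r <= 2^(1/6) sigma, exactly zero beyond.
#'
#' @inheritParams lj_energy_force
#' @export
wca_energy_force <- function(r, pp) {
  stopifnot(inherits(pp, "pair_params"))
  if (any(r <= 0)) stop("r must be positive")
  out <- cpp_pair_potential(r, pp$sigma_ij, pp$epsilon_ij, 1L, Inf,
                            1.0, 0.5, 1L, 0.3)
  list(energy = out$energy, force = out$force)
}

#' Soft-core WCA energy and dU/dlambda
#'
#' Beutler-form coupling `V(r; lambda) = lambda * V_WCA(rsc)` with
#' `rsc = (alpha sigma_sc^6 (1-lambda)^p + r^6)^(1/6)`. At `lam = 1` this
#' reduces exactly to [wca_energy_force()]; at `lam = 0` the energy vanishes
#' and dU/dlambda stays finite for all r >= 0.
#'
#' @inheritParams lj_energy_force
#' @param lam Coupling parameter in \[0, 1\].
#' @param sc A [softcore_params()].
#' @return List with `energy`, `force`, `dudl`.
#' @export
softcore_energy_dudl <- function(r, pp, lam, sc = softcore_params()) {
  stopifnot(inherits(pp, "pair_params"))
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  out <- cpp_pair_potential(r, pp$sigma_ij, pp$epsilon_ij, 2L, Inf,
                            lam, sc$alpha, sc$p, sc$sigma_sc)
  list(energy = out$energy, force = out$force, dudl = out$dudl)
}

#' Build a force-field table from a species list
#'
#' Applies Lorentz-Berthelot mixing (`sigma_ij = (sigma_i + sigma_j)/2`,
#' `epsilon_ij = sqrt(epsilon_i epsilon_j)`), then multiplies polymer-water
#' well depths by `scaling$lambda_pw` and polymer-alcohol ones by
#' `scaling$lambda_pa`, leaving diameters unchanged. Optionally a
#' water-alcohol cross factor `xi_wa` scales the solvent-cosolvent well depth
#' (the knob that makes the reduced cosolvent interfacially active). With
#' `wca_polymer_solvent = TRUE` all polymer-(co)solvent pairs become purely
#' repulsive WCA, the interaction used for cavity (excluded-volume) work.
#'
#' @param species_tbl Tibble of [species()] rows.
#' @param scaling A [lambda_scaling()].
#' @param wca_polymer_solvent Use WCA for polymer-(co)solvent pairs?
#' @param xi_wa Water-alcohol cross-interaction factor (default 1).
#' @param cutoff LJ truncation (nm).
#' @param softcore A [softcore_params()] used when pairs are set to soft-core
#'   mode during thermodynamic integration.
#' @param lambda Current soft-core coupling value.
#' @return A `forcefield` object.
#' @export
build_forcefield <- function(species_tbl, scaling = lambda_scaling(),
                             wca_polymer_solvent = FALSE, xi_wa = 1.0,
                             cutoff = 1.4, softcore = softcore_params(),
                             lambda = 1.0) {
  stopifnot(is.data.frame(species_tbl), nrow(species_tbl) >= 1)
  if (!all(species_tbl$role %in% c("polymer", "water", "alcohol")))
    stop("unknown species role; must be polymer, water or alcohol")
  n <- nrow(species_tbl)
  sig <- outer(species_tbl$sigma, species_tbl$sigma, function(a, b) (a + b) / 2)
  eps <- outer(species_tbl$epsilon, species_tbl$epsilon,
               function(a, b) sqrt(a * b))
  role <- species_tbl$role
  pw <- outer(role == "polymer", role == "water") |
    outer(role == "water", role == "polymer")
  pa <- outer(role == "polymer", role == "alcohol") |
    outer(role == "alcohol", role == "polymer")
  wa <- outer(role == "water", role == "alcohol") |
    outer(role == "alcohol", role == "water")
  eps[pw] <- eps[pw] * scaling$lambda_pw
  eps[pa] <- eps[pa] * scaling$lambda_pa
  eps[wa] <- eps[wa] * xi_wa
  mode <- matrix(0L, n, n)
  if (wca_polymer_solvent) mode[pw | pa] <- 1L
  dimnames(sig) <- dimnames(eps) <- dimnames(mode) <-
    list(species_tbl$name, species_tbl$name)
  structure(list(species = tibble::as_tibble(species_tbl), sigma_ij = sig,
                 eps_ij = eps, mode_ij = mode, cutoff = cutoff,
                 softcore = softcore, lambda = lambda, scaling = scaling,
                 xi_wa = xi_wa),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat("<forcefield> ", nrow(x$species), " species, cutoff ", x$cutoff,
      " nm, lambda ", x$lambda, "\n", sep = "")
  print(x$species)
  invisible(x)
}

#' Set the interaction mode for role pairs
#'
#' @param ff A `forcefield`.
#' @param role_a,role_b Role names.
#' @param mode `"LJ"`, `"WCA"`, `"softcore"` or `"excluded"`.
#' @export
set_pair_mode <- function(ff, role_a, role_b, mode) {
  code <- mode_code(match.arg(mode, c("LJ", "WCA", "softcore", "excluded")))
  role <- ff$species$role
  sel <- outer(role == role_a, role == role_b) |
    outer(role == role_b, role == role_a)
  ff$mode_ij[sel] <- code
  ff
}

#' Set the current soft-core coupling of a force field
#' @param ff A `forcefield`.
#' @param lambda Coupling in \[0, 1\].
#' @export
set_lambda <- function(ff, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  ff$lambda <- lambda
  ff
}

#' Default species of the reduced model
#'
#' The generic polymer bead (sigma 0.4 nm, epsilon 1.0 kJ/mol) plus a one-site
#' water-like solvent and a one-site methanol-like or two-site ethanol-like
#' cosolvent. The apolar solvent parameters fold hydrogen-bond cohesion into
#' the LJ well depth so the fluids are liquid at 300 K; the alcohol site is
#' larger and less cohesive than water, the asymmetry that makes it
#' interfacially active.
#'
#' @param alcohol `"methanol"` (1 site) or `"ethanol"` (2 bonded sites).
#' @return A species tibble (polymer, water, alcohol site).
#' @export
default_species <- function(alcohol = c("methanol", "ethanol")) {
  alcohol <- match.arg(alcohol)
  dplyr::bind_rows(
    species("P", 0.40, 1.0, 40, "polymer"),
    species("W", 0.30, 3.7, 18, "water"),
    if (alcohol == "methanol") species("M", 0.45, 3.0, 32, "alcohol")
    else species("E", 0.40, 2.4, 23, "alcohol"))
}
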