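#' Default campaign configuration
#'
#' Nested list mirroring the full pipeline: force-field block, system block,
#' umbrella block, TI block, analysis block, master seed and output
#' directory. Every default carries its provenance ("production protocol" of
#' the collapse study versus a package decision) in the `provenance`
#' attribute.
#'
#' @return A `campaign_config` list.
#' @export
default_config <- function() {
  cfg <- list(
    forcefield = list(
      sigma_p = 0.4, epsilon_p = 1.0,          # nm, kJ/mol
      lambda_pw = 1.095, lambda_pa = 0.949,    # dimensionless
      xi_wa = 0.90, cutoff = 1.4,              # dimensionless, nm
      alcohol = "methanol"),
    system = list(
      n_beads = 32L, n_solvent = NULL, # NULL: derive from box volume
      x_grid = c(0.05, 0.1, 0.2, 0.35), clearance = 0.6,
      temperature = 300, pressure_atm = 1),
    umbrella = list(
      rg_min = 0.4, rg_max = 1.2, spacing = 0.025,   # nm
      k_b = 20000,                                    # kJ/mol/nm^2
      rg_cut = 0.7,                                   # nm
      n_equil_steps = 500L, n_prod_steps = 5000L, bin_width = 0.01),
    ti = list(
      n_lambda = 21L, lambda_power = 1, sc_alpha = 0.5, sc_p = 1L,
      sc_sigma = 0.3, k_pr = 1e5, n_equil_steps = 500L,
      n_prod_steps = 2500L),
    analysis = list(
      shell_cutoff = 0.55, probe = 0.14, sasa_points = 960L),
    integrator = list(dt = 0.002, friction_time = 0.1),
    master_seed = 1L,
    outdir = "results")
  attr(cfg, "provenance") <- list(
    production = c("forcefield.sigma_p", "forcefield.epsilon_p",
                   "forcefield.lambda_pw", "forcefield.lambda_pa",
                   "forcefield.cutoff", "system.n_beads",
                   "system.temperature", "system.pressure_atm",
                   "umbrella.rg_min", "umbrella.rg_max", "umbrella.spacing",
                   "umbrella.k_b", "umbrella.rg_cut", "ti.n_lambda",
                   "ti.sc_alpha", "ti.sc_p", "ti.sc_sigma", "ti.k_pr",
                   "integrator.dt", "integrator.friction_time"),
    decision = c("forcefield.xi_wa", "forcefield.alcohol",
                 "system.n_solvent", "system.x_grid", "system.clearance",
                 "umbrella.n_equil_steps", "umbrella.n_prod_steps",
                 "umbrella.bin_width", "ti.lambda_power", "ti.n_equil_steps",
                 "ti.n_prod_steps", "analysis.shell_cutoff",
                 "analysis.probe", "analysis.sasa_points", "master_seed",
                 "outdir"))
  class(cfg) <- "campaign_config"
  cfg
}

validate_config <- function(cfg) {
  ref <- default_config()
  for (blk in names(cfg)) {
    if (!blk %in% names(ref))
      stop("unknown config block: ", blk)
    if (is.list(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), names(ref[[blk]]))
      if (length(bad))
        stop("unknown config key: ", blk, ".", bad[1])
    }
  }
  num_pos <- c("forcefield.sigma_p", "forcefield.cutoff",
               "system.temperature", "umbrella.spacing", "umbrella.k_b",
               "ti.sc_sigma", "integrator.dt", "integrator.friction_time")
  for (key in num_pos) {
    p <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- cfg[[p[1]]][[p[2]]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      stop("config key ", key, " must be a positive number ",
           "(nm / K / kJ/mol units as documented)")
  }
  if (!is.null(cfg$system$x_grid) &&
      any(cfg$system$x_grid < 0 | cfg$system$x_grid > 1))
    stop("config key system.x_grid must lie in [0, 1] (mole fraction)")
  invisible(cfg)
}

#' Load a campaign configuration
#'
#' Reads a YAML file, fills unset keys from [default_config()] and validates
#' (unknown keys are rejected; units are documented per key). An empty file
#' yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A validated `campaign_config`.
#' @export
load_config <- function(path) {
  user <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  prov <- attr(cfg, "provenance")
  for (blk in names(user)) {
    if (!blk %in% names(cfg)) stop("unknown config block: ", blk)
    if (is.list(user[[blk]]))
      cfg[[blk]] <- utils::modifyList(cfg[[blk]], user[[blk]])
    else cfg[[blk]] <- user[[blk]]
  }
  attr(cfg, "provenance") <- prov
  class(cfg) <- "campaign_config"
  validate_config(cfg)
}

#' Save a campaign configuration
#' @param cfg A `campaign_config`.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# TSV with commented metadata header

#' Write a table as TSV with a commented metadata header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named list written as `# key: value` lines.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path File path.
#' @return Tibble with a `meta` attribute.
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^# ", "", l)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.table(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                       collapse = "\n"),
                          header = TRUE, sep = "\t")
  out <- tibble::as_tibble(df)
  attr(out, "meta") <- meta
  out
}

#' Write result tables and a manifest
#'
#' Each element of `results` (a data frame) is written as a TSV named after
#' its list name; the manifest records file names, md5 hashes and the seed.
#'
#' @param results Named list of data frames.
#' @param outdir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return Tibble manifest (also written to `manifest.tsv`).
#' @export
write_results_tables <- function(results, outdir, seed = NA_integer_) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (nm in names(results)) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    write_tsv_meta(as.data.frame(results[[nm]]), path,
                   meta = list(table = nm, seed = seed))
    rows[[nm]] <- tibble::tibble(table = nm, file = basename(path),
                                 md5 = unname(tools::md5sum(path)),
                                 rows = nrow(results[[nm]]))
  }
  manifest <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(table = character(), file = character(),
                   md5 = character(), rows = integer())
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

# ---------------------------------------------------------------------------
# extended XYZ

#' Write frames as extended XYZ
#'
#' The comment line carries `step`, `box` (Lattice) and the potential-energy
#' terms when present.
#'
#' @param sys An `md_system` (or list of them).
#' @param path Output path.
#' @param append Append to an existing file?
#' @export
write_extxyz <- function(sys, path, append = FALSE) {
  frames <- if (inherits(sys, "md_system")) list(sys) else sys
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$x)
    lat <- sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g"', fr$box[1], fr$box[2],
                   fr$box[3])
    writeLines(as.character(n), con)
    writeLines(paste0(lat, ' Properties=species:S:1:pos:R:3 step=', fr$step),
               con)
    nm <- fr$species$name[fr$sp]
    writeLines(sprintf("%s %.8f %.8f %.8f", nm, fr$x[, 1], fr$x[, 2],
                       fr$x[, 3]), con)
  }
  invisible(path)
}

#' Read extended-XYZ frames
#'
#' @param path File path.
#' @param species_tbl Species tibble used to map labels to indices.
#' @return List of `md_system` frames.
#' @export
read_extxyz <- function(path, species_tbl) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cmt <- lines[i + 1]
    lat <- regmatches(cmt, regexpr('Lattice="[^"]*"', cmt))
    box <- as.numeric(strsplit(sub('Lattice="', "", sub('"$', "", lat)),
                               " ")[[1]])[c(1, 5, 9)]
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", cmt))
    rows <- strsplit(lines[(i + 2):(i + 1 + n)], "[ \t]+")
    nm <- vapply(rows, `[[`, character(1), 1)
    x <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <-
      md_system(x, box, match(nm, species_tbl$name), species_tbl,
                step = step)
    i <- i + 2 + n
  }
  frames
}

# ---------------------------------------------------------------------------
# end-to-end scan driver

#' Composition scan of the excluded-volume collapse driving force
#'
#' The end-to-end campaign behind the cavity-work analysis: for each
#' composition in the grid, cavity TI for frozen coil and globule snapshots
#' plus the adsorption campaign, yielding the cavity-work curves, their
#' difference with its interior minimum, first-shell occupancies and the
#' saturation composition.
#'
#' @param cfg A `campaign_config` (see [default_config()]).
#' @param preset `"tiny"` shrinks the protocol for smoke runs.
#' @param write_tables Write TSVs to `cfg$outdir`?
#' @return List with `cavity` (ti_campaign output), `adsorption`,
#'   `saturation`, and `manifest` (when written).
#' @export
run_cononsolvency_scan <- function(cfg = default_config(), preset = NULL,
                                   write_tables = FALSE) {
  if (!is.null(preset) && preset == "tiny") {
    cfg$system$n_beads <- 12L
    cfg$system$x_grid <- c(0.1, 0.3)
    cfg$system$clearance <- 0.45
    cfg$ti$n_lambda <- 6L
    cfg$ti$lambda_power <- 2
    cfg$ti$n_equil_steps <- 100L
    cfg$ti$n_prod_steps <- 400L
  }
  spec_solv <- reduced_solvent_spec(cfg$forcefield$alcohol,
                                    xi_wa = cfg$forcefield$xi_wa)
  ispec <- integrator_spec(dt = cfg$integrator$dt,
                           temperature = cfg$system$temperature,
                           friction_time = cfg$integrator$friction_time)
  coil <- make_conformers(cfg$system$n_beads, "coil",
                          seed = derive_seed(cfg$master_seed, 41L))
  glob <- make_conformers(cfg$system$n_beads, "globule",
                          seed = derive_seed(cfg$master_seed, 42L))
  sched <- lambda_schedule(cfg$ti$n_lambda, power = cfg$ti$lambda_power)
  cav <- ti_campaign(coil, glob, spec_solv, cfg$system$x_grid,
                     n_solvent = cfg$system$n_solvent,
                     clearance = cfg$system$clearance, schedule = sched,
                     spec = ispec, n_equil = cfg$ti$n_equil_steps,
                     n_prod = cfg$ti$n_prod_steps,
                     seed = derive_seed(cfg$master_seed, 43L),
                     k_pr = cfg$ti$k_pr)
  ads <- adsorption_campaign(coil, glob, spec_solv, cfg$system$x_grid,
                             n_solvent = cfg$system$n_solvent,
                             clearance = cfg$system$clearance, spec = ispec,
                             n_equil = cfg$ti$n_equil_steps,
                             n_prod = 2L * cfg$ti$n_prod_steps,
                             shell_cutoff = cfg$analysis$shell_cutoff,
                             seed = derive_seed(cfg$master_seed, 44L))
  gl <- ads[ads$conformation == "globule", ]
  sat <- saturation_concentration(
    tibble::tibble(x_alcohol = gl$x_alcohol, n_shell = gl$n_shell))
  out <- list(cavity = cav, adsorption = ads, saturation = sat)
  if (write_tables) {
    out$manifest <- write_results_tables(
      list(cavity_work = cav$table, cavity_difference = cav$ddg,
           adsorption = as.data.frame(ads)),
      cfg$outdir, seed = cfg$master_seed)
  }
  out
}
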