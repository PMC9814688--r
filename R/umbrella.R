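#' Generate umbrella-sampling windows along R_g
#'
#' Inclusive arithmetic grid of restraint targets; the production grid of
#' the collapse study runs from 0.4 to 1.2 nm in steps of 0.025 nm
#' (33 windows) with k_b = 20000 kJ/mol/nm^2. Each window receives a seed
#' derived from the master seed so any window is reproducible in isolation.
#'
#' @param rg_min,rg_max Grid limits (nm).
#' @param spacing Window spacing (nm).
#' @param k_b Restraint force constant (kJ/mol/nm^2).
#' @param n_equil_steps,n_prod_steps Equilibration/production steps.
#' @param master_seed Master seed.
#' @return Tibble of windows (`rg0`, `k_b`, steps, `seed`).
#' @export
generate_windows <- function(rg_min = 0.4, rg_max = 1.2, spacing = 0.025,
                             k_b = 20000, n_equil_steps = 500,
                             n_prod_steps = 5000, master_seed = 1L) {
  stopifnot(rg_min <= rg_max, spacing > 0, n_prod_steps > 0)
  if (rg_min < rg_max && spacing > (rg_max - rg_min))
    stop("spacing exceeds the sampling range")
  n <- floor((rg_max - rg_min) / spacing + 1e-9) + 1
  rg0 <- rg_min + (seq_len(n) - 1) * spacing
  tibble::tibble(rg0 = rg0, k_b = k_b, n_equil_steps = n_equil_steps,
                 n_prod_steps = n_prod_steps,
                 seed = vapply(seq_len(n), function(i)
                   derive_seed(master_seed, 1L, i), integer(1)))
}

#' Bin R_g samples from umbrella windows into a histogram set
#'
#' @param samples Named list of numeric R_g sample vectors, one per window
#'   (in window order), or a tibble with `window` and `rg` columns.
#' @param windows Windows tibble from [generate_windows()].
#' @param bin_width Histogram bin width (nm), default 0.01.
#' @param range Histogram range; defaults to the sample range padded by one
#'   bin.
#' @param temperature Temperature (K).
#' @return A `histogram_set`.
#' @export
histogram_set <- function(samples, windows, bin_width = 0.01, range = NULL,
                          temperature = 300) {
  if (is.data.frame(samples))
    samples <- split(samples$rg, samples$window)
  stopifnot(length(samples) == nrow(windows))
  allr <- unlist(samples)
  if (is.null(range))
    range <- c(min(allr) - bin_width, max(allr) + bin_width)
  edges <- seq(floor(range[1] / bin_width) * bin_width,
               ceiling(range[2] / bin_width) * bin_width, by = bin_width)
  counts <- vapply(samples, function(s)
    graphics::hist(s, breaks = edges, plot = FALSE)$counts,
    numeric(length(edges) - 1))
  if (any(colSums(counts) == 0)) stop("a window produced no samples")
  structure(list(bin_edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, windows = windows,
                 temperature = temperature),
            class = "histogram_set")
}

#' @export
print.histogram_set <- function(x, ...) {
  cat("<histogram_set> ", ncol(x$counts), " windows, ", nrow(x$counts),
      " bins on [", min(x$bin_edges), ", ", max(x$bin_edges), "] nm\n",
      sep = "")
  invisible(x)
}

#' Reconstruct the unbiased PMF by WHAM
#'
#' Self-consistent weighted-histogram iteration:
#' `P(b) = sum_i n_i(b) / sum_i N_i exp((F_i - V_i(b))/RT)` with
#' `F_i = -RT log sum_b P(b) exp(-V_i(b)/RT)`, iterated until the largest
#' change in any window free energy falls below `tol` (in units of RT). The
#' profile `w = -RT log P` is anchored so its minimum over well-sampled bins
#' is zero. Uncertainties come from a Bayesian bootstrap over windows
#' (Dirichlet window weights).
#'
#' @param h A [histogram_set()].
#' @param tol Convergence tolerance on window free energies (RT units).
#' @param max_iter Iteration cap.
#' @param n_boot Bayesian bootstrap resamples (0 disables).
#' @param seed Bootstrap seed.
#' @param min_overlap Warn when adjacent windows share fewer common-bin
#'   counts than this.
#' @return A `pmf_profile`: tibble (`rg`, `w`, `stderr`) with attributes
#'   `temperature`, `f_windows`, `iterations`, `boot_w`.
#' @export
wham_solve <- function(h, tol = 1e-8, max_iter = 1e5, n_boot = 50,
                       seed = 1L, min_overlap = 10) {
  stopifnot(inherits(h, "histogram_set"))
  RT <- thermal_energy(h$temperature)
  counts <- h$counts
  W <- ncol(counts)
  # overlap diagnostic on adjacent windows
  if (W > 1) {
    for (i in seq_len(W - 1)) {
      common <- pmin(counts[, i] > 0, counts[, i + 1] > 0)
      ov <- sum(pmin(counts[, i], counts[, i + 1])[common == 1])
      if (ov < min_overlap)
        warning(sprintf("windows %d and %d share only %d counts", i, i + 1,
                        ov))
    }
  }
  V <- outer(h$centers, seq_len(W),
             function(x, i) 0.5 * h$windows$k_b[i] * (x - h$windows$rg0[i])^2)
  core <- function(counts, Ni) {
    M <- rowSums(counts)
    keep <- M > 0
    expnbv <- exp(-V / RT)
    f <- rep(0, W)
    for (it in seq_len(max_iter)) {
      denom <- as.vector(expnbv %*% (Ni * exp(f / RT)))
      P <- ifelse(keep, M / denom, 0)
      P <- P / sum(P)
      fnew <- -RT * log(colSums(P * expnbv))
      fnew <- fnew - fnew[1]
      df <- max(abs(fnew - f)) / RT
      f <- fnew
      if (df < tol) return(list(P = P, f = f, it = it))
    }
    stop(paste0("WHAM did not converge in ", max_iter,
                " iterations; last max |dF|/RT = ", signif(df, 3)))
  }
  Ni <- colSums(counts)
  sol <- core(counts, Ni)
  w <- ifelse(sol$P > 0, -RT * log(sol$P), NA_real_)
  w <- w - min(w, na.rm = TRUE)
  boot_w <- NULL
  stderr <- rep(NA_real_, length(w))
  if (n_boot > 0 && W > 1) {
    set.seed(seed)
    boot_w <- matrix(NA_real_, length(w), n_boot)
    for (b in seq_len(n_boot)) {
      g <- rexp(W); g <- g / mean(g)
      cb <- sweep(counts, 2, g, "*")
      sb <- core(cb, colSums(cb))
      wb <- ifelse(sb$P > 0, -RT * log(sb$P), NA_real_)
      boot_w[, b] <- wb - min(wb, na.rm = TRUE)
    }
    stderr <- apply(boot_w, 1, stats::sd, na.rm = TRUE)
  }
  out <- tibble::tibble(rg = h$centers, w = w, stderr = stderr)
  structure(out, class = c("pmf_profile", class(out)),
            temperature = h$temperature, f_windows = sol$f,
            iterations = sol$it, boot_w = boot_w, anchor = "min(w) = 0")
}

#' Build a PMF profile from tabulated values
#'
#' @param rg,w Knots (nm, kJ/mol).
#' @param temperature Temperature (K).
#' @param stderr Optional standard errors.
#' @export
pmf_profile <- function(rg, w, temperature = 300, stderr = NA_real_) {
  out <- tibble::tibble(rg = rg, w = w - min(w, na.rm = TRUE),
                        stderr = stderr)
  structure(out, class = c("pmf_profile", class(out)),
            temperature = temperature, anchor = "min(w) = 0")
}

#' Collapse free energy from a PMF (two-state integral)
#'
#' `exp(-dG/RT) = I_globule / I_coil` with
#' `I = int exp(-w(Rg)/RT) dRg` taken below and above `rg_cut`. The profile
#' is treated as piecewise linear between tabulated knots and each segment is
#' integrated on a refined trapezoidal grid, so the result is invariant to
#' adding a constant to `w` and the upper "infinite" limit truncates at the
#' last finite bin. Negative dG means the globule is favoured.
#'
#' @param pmf A `pmf_profile`.
#' @param rg_cut Coil/globule boundary (nm), default 0.7.
#' @param temperature Temperature (K); defaults to the profile's.
#' @param refine Sub-points per tabulated segment.
#' @return List with `dg` and `stderr` (bootstrap-propagated when the
#'   profile carries bootstrap replicates).
#' @export
collapse_free_energy <- function(pmf, rg_cut = 0.7, temperature = NULL,
                                 refine = 64) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(temperature))
    temperature <- attr(pmf, "temperature") %||% 300
  RT <- thermal_energy(temperature)
  ok <- is.finite(pmf$w)
  rg <- pmf$rg[ok]; w <- pmf$w[ok]
  if (rg_cut <= min(rg) || rg_cut >= max(rg))
    stop("rg_cut lies outside the sampled PMF grid")
  dg_of <- function(rg, w) {
    side <- function(lo, hi) {
      x <- unique(sort(c(seq(lo, hi, length.out = max(2, refine *
        ceiling((hi - lo) / mean(diff(rg)))) ), rg[rg >= lo & rg <= hi])))
      y <- exp(-stats::approx(rg, w, xout = x, rule = 2)$y / RT)
      sum((y[-1] + y[-length(y)]) / 2 * diff(x))
    }
    -RT * log(side(min(rg), rg_cut) / side(rg_cut, max(rg)))
  }
  dg <- dg_of(rg, w)
  bw <- attr(pmf, "boot_w")
  se <- NA_real_
  if (!is.null(bw)) {
    reps <- apply(bw, 2, function(wb) {
      okb <- is.finite(wb)
      if (sum(okb) < 3) return(NA_real_)
      dg_of(pmf$rg[okb], wb[okb])
    })
    se <- stats::sd(reps, na.rm = TRUE)
  }
  list(dg = dg, stderr = se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an umbrella-sampling campaign
#'
#' Simulates each window (seeded independently; windows are chained so each
#' starts from the previous window's final state), discards equilibration,
#' accumulates R_g histograms, solves WHAM and applies the two-state
#' integral.
#'
#' @param sys Starting `md_system` containing the polymer.
#' @param ff A `forcefield`.
#' @param windows Tibble from [generate_windows()].
#' @param spec An [integrator_spec()].
#' @param stride Sampling stride (steps).
#' @param bin_width Histogram bin width (nm).
#' @param rg_cut Coil/globule boundary for the collapse integral (nm).
#' @param n_boot Bootstrap resamples for WHAM errors.
#' @param progress Print per-window progress?
#' @param selection Restrained particle indices (default: polymer beads, or
#'   every particle when the system has no polymer role).
#' @param restraints Additional restraints applied in every window.
#' @return List with `histograms`, `pmf`, `dg` (list dg/stderr), `records`.
#' @export
umbrella_campaign <- function(sys, ff, windows, spec = integrator_spec(),
                              stride = 10L, bin_width = 0.01, rg_cut = 0.7,
                              n_boot = 50, progress = FALSE,
                              selection = NULL, restraints = list()) {
  sel <- selection %||% polymer_selection(sys)
  if (length(sel) < 2) sel <- seq_len(nrow(sys$x))
  samples <- vector("list", nrow(windows))
  state <- sys
  for (i in seq_len(nrow(windows))) {
    wdw <- windows[i, ]
    res <- c(list(rg_restraint(wdw$rg0, wdw$k_b, sel)), restraints)
    if (wdw$n_equil_steps > 0)
      state <- run_segment(state, ff, spec, wdw$n_equil_steps,
                           restraints = res,
                           seed = derive_seed(wdw$seed, 2L), stride = 0L
                           )$system
    out <- run_segment(state, ff, spec, wdw$n_prod_steps,
                       restraints = res,
                       seed = derive_seed(wdw$seed, 3L), stride = stride)
    state <- out$system
    samples[[i]] <- out$records$rg
    if (progress)
      message(sprintf("window %d/%d rg0=%.3f <rg>=%.3f", i, nrow(windows),
                      wdw$rg0, mean(out$records$rg)))
  }
  h <- histogram_set(samples, windows, bin_width = bin_width,
                     temperature = spec$temperature)
  pmf <- wham_solve(h, n_boot = n_boot)
  dg <- tryCatch(collapse_free_energy(pmf, rg_cut),
                 error = function(e) list(dg = NA_real_, stderr = NA_real_))
  list(histograms = h, pmf = pmf, dg = dg,
       records = tibble::tibble(window = rep(seq_along(samples),
                                             lengths(samples)),
                                rg = unlist(samples)))
}
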