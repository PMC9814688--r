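# shared fixtures: tiny systems, independent reference implementations

RT300 <- cononsolv::thermal_energy(300)

# plain-R reference LJ/WCA evaluation (independent of the compiled kernels)
ref_lj <- function(r, sigma, eps, cutoff = 1.4) {
  ifelse(r >= cutoff, 0, 4 * eps * ((sigma / r)^12 - (sigma / r)^6))
}
ref_wca <- function(r, sigma, eps) {
  rmin <- 2^(1 / 6) * sigma
  ifelse(r >= rmin, 0, ref_lj(r, sigma, eps, Inf) + eps)
}

# central finite-difference gradient of a scalar function of an N x 3 matrix
num_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_len(nrow(x))) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    g[i, d] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# small argon-like one-species fluid for engine tests
tiny_fluid <- function(n = 50, box = 2.5, sigma = 0.34, eps = 1.0,
                       seed = 42, jitter = TRUE) {
  sp <- cononsolv::species("Ar", sigma, eps, 40, "water")
  m <- ceiling(n^(1 / 3))
  g <- expand.grid(x = 1:m, y = 1:m, z = 1:m)[1:n, ]
  x <- as.matrix(g) * box / m
  if (jitter) {
    set.seed(seed)
    x <- x + matrix(rnorm(3 * n, sd = 0.02), n, 3)
  }
  list(sys = cononsolv::md_system(x, box, rep(1L, n), sp),
       ff = cononsolv::build_forcefield(sp, cutoff = 1.2))
}

# 32-bead polymer with bonded terms in vacuum
tiny_polymer <- function(n = 12, seed = 3) {
  cononsolv::make_conformers(n, "coil", seed = seed,
                             target_rg = 0.35 * sqrt(n / 12) * 2)
}

# all-pairs reference energy for one-species LJ fluid with minimum image
ref_pair_energy <- function(x, box, sigma, eps, cutoff) {
  n <- nrow(x)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- x[i, ] - x[j, ]
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    e <- e + ref_lj(r, sigma, eps, cutoff)
  }
  e
}
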