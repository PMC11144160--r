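# Shared fixtures and the independent brute-force assignment oracle.

# A small isoscape built directly from a matrix (row 1 = north).
mk_iso <- function(values, extent = c(0, ncol(values), 0, nrow(values)),
                   sigma = 12, isotope = "d2H", calibrated = TRUE) {
  isoscape(values, extent, sigma = sigma, isotope = isotope,
           calibrated = calibrated)
}

# Fast small configuration for generator tests.
small_config <- function(seed = 1,
                         year_counts = c("2007" = 20L, "2008" = 20L,
                                         "2009" = 20L), ...) {
  sim_config(seed = seed,
             grid_shape = c(20L, 20L),
             year_counts = year_counts,
             ...)
}

# Independent oracle: cell-by-cell normal densities with explicit loops,
# then an explicit highest-probability cumulative set. Deliberately naive.
oracle_posterior <- function(d2H, d13C, h_surface, c_surface,
                             sigma_h, sigma_c) {
  nr <- nrow(h_surface$values)
  nc <- ncol(h_surface$values)
  dens <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      mh <- h_surface$values[i, j]
      mc <- c_surface$values[i, j]
      if (!is.na(mh) && !is.na(mc)) {
        dens[i, j] <- dnorm(d2H, mh, sigma_h) * dnorm(d13C, mc, sigma_c)
      }
    }
  }
  dens / sum(dens, na.rm = TRUE)
}

oracle_odds <- function(prob, mass = 2 / 3) {
  v <- as.vector(prob)
  ord <- order(v, decreasing = TRUE, na.last = NA)
  cum <- 0
  included <- rep(FALSE, length(v))
  k <- 0
  for (ix in ord) {
    if (cum >= mass - 1e-12) break
    included[ix] <- TRUE
    cum <- cum + v[ix]
    k <- ix
  }
  # tie rule: include every cell matching the last included probability
  if (any(included)) {
    p_last <- min(v[included])
    included[!is.na(v) & v >= p_last - 1e-15] <- TRUE
  }
  ind <- matrix(NA_integer_, nrow(prob), ncol(prob))
  ind[!is.na(v)] <- 0L
  ind[included] <- 1L
  ind
}
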