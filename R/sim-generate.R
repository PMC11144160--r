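# Synthetic-data generator: isoscapes, roster, true origins, feather values,
# winter environmental indices, and return outcomes. The generator plants the
# models the analysis chain assumes, so downstream fits can be validated by
# parameter recovery.

#' Generate synthetic precipitation-deuterium and plant-carbon isoscapes
#'
#' Each surface is a planar large-scale gradient (deuterium west to east,
#' carbon south to north, so the two are not collinear and dual-isotope
#' assignment is identifiable) plus small-amplitude, spatially correlated
#' (gaussian-smoothed) noise. A configurable fraction of cells is masked in
#' smooth blobs, mimicking ocean or out-of-range areas. Deterministic given
#' the configuration seed. With zero noise amplitude the surfaces equal the
#' planar gradients exactly.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{h} (precipitation deuterium
#'   \code{isoscape}, uncalibrated) and \code{c} (plant carbon
#'   \code{isoscape}, undiscriminated), co-registered on one grid.
#' @export
make_isoscapes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nr <- config$grid_shape[1]
  nc <- config$grid_shape[2]
  ip <- config$isoscape_params
  # cell-center normalized positions: 0 at the first cell, 1 at the last
  xn <- if (nc > 1) (seq_len(nc) - 1) / (nc - 1) else 0
  yn <- if (nr > 1) (seq_len(nr) - 1) / (nr - 1) else 0  # row 1 = north
  h_plane <- matrix(rep(ip$h_range[1] + diff(ip$h_range) * xn, each = nr),
                    nr, nc)
  # carbon: c_range[1] at the southernmost row up to c_range[2] northernmost
  c_plane <- matrix(rep(ip$c_range[2] - diff(ip$c_range) * yn, times = nc),
                    nr, nc)
  with_stage_seed(config$seed, "isoscape", {
    noise_field <- function(amp) {
      if (amp == 0) return(matrix(0, nr, nc))
      z <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                         ip$noise_scale)
      amp * (z - mean(z)) / stats::sd(z)
    }
    h_vals <- h_plane + noise_field(ip$noise_amp[["H"]])
    c_vals <- c_plane + noise_field(ip$noise_amp[["C"]])
    if (ip$mask_fraction > 0) {
      blob <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                            ip$noise_scale)
      cut <- stats::quantile(blob, 1 - ip$mask_fraction)
      masked <- blob > cut
      h_vals[masked] <- NA_real_
      c_vals[masked] <- NA_real_
    }
    sigma_h <- sqrt(config$sigma_resid_cal^2 + config$sigma_meas[["H"]]^2)
    sigma_c <- config$sigma_meas[["C"]]
    list(h = isoscape(h_vals, config$extent,
                      sigma = if (sigma_h > 0) sigma_h else NA_real_,
                      isotope = "d2H", calibrated = FALSE),
         c = isoscape(c_vals, config$extent,
                      sigma = if (sigma_c > 0) sigma_c else NA_real_,
                      isotope = "d13C", calibrated = FALSE))
  })
}

#' Build the study roster
#'
#' One record per individual-year, matching the configured per-year counts
#' exactly. A configured fraction of individuals is sampled in two
#' consecutive years (their age advances young to old); all others appear
#' once. Each new individual receives a latent blackness drawn uniformly
#' from the blackness grid, emulating deliberate balanced sampling of the
#' coloration range in each year; latent blackness is the habitat-placement
#' score and is constant within an individual.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{roster} (data.frame: id, year, age,
#'   latent_blackness) and \code{n_repeat} (number of individuals appearing
#'   in more than one year).
#' @export
make_roster <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$year_counts
  years <- as.integer(names(counts))
  ord <- order(years)
  years <- years[ord]
  counts <- as.integer(counts[ord])
  n_total <- sum(counts)
  f <- config$repeat_fraction
  n_repeat <- if (length(years) > 1) round(f * n_total / (1 + f)) else 0L
  n_trans <- max(length(years) - 1L, 1L)
  carry <- rep(n_repeat %/% n_trans, n_trans)
  extra <- n_repeat %% n_trans
  if (extra > 0) carry[seq(n_trans - extra + 1, n_trans)] <-
      carry[seq(n_trans - extra + 1, n_trans)] + 1L
  carry <- pmin(carry, pmin(counts[-length(counts)], counts[-1]))
  if (length(years) > 1 && sum(carry) < n_repeat) {
    warning("per-year counts cannot host ", n_repeat,
            " repeated individuals; using ", sum(carry))
  }
  with_stage_seed(config$seed, "roster", {
    next_id <- 1L
    new_ind <- function(n) {
      ids <- sprintf("FP%04d", seq(next_id, next_id + n - 1L))
      next_id <<- next_id + n
      data.frame(
        id = ids,
        age = ifelse(stats::runif(n) < config$age_young_prob,
                     "young", "old"),
        latent_blackness = sample(config$blackness_grid, n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    rows <- list()
    prev <- NULL
    for (t in seq_along(years)) {
      n_carry <- if (t == 1) 0L else carry[t - 1]
      carried <- if (n_carry > 0) {
        # carry forward individuals new in the previous year (each
        # individual appears at most twice)
        pool <- prev[prev$new, , drop = FALSE]
        pick <- pool[sample.int(nrow(pool), n_carry), , drop = FALSE]
        data.frame(id = pick$id, age = "old",
                   latent_blackness = pick$latent_blackness,
                   stringsAsFactors = FALSE)
      } else NULL
      fresh <- new_ind(counts[t] - n_carry)
      yr <- rbind(
        if (!is.null(carried)) cbind(carried, new = FALSE),
        cbind(fresh, new = TRUE))
      yr$year <- years[t]
      rows[[t]] <- yr
      prev <- yr
    }
    roster <- do.call(rbind, rows)
    roster <- roster[, c("id", "year", "age", "latent_blackness")]
    rownames(roster) <- NULL
    list(roster = roster,
         n_repeat = sum(table(roster$id) > 1))
  })
}

#' Place true moult origins on the isoscape grid
#'
#' Each record's true origin cell is drawn from cells whose calibrated
#' feather-deuterium value lies within a tolerance of the target implied by
#' inverting the planted blackness-deuterium line (blacker individuals get
#' lower-deuterium, wetter cells), with the full inverse span rescaled into
#' the configured target half-width so targets stay inside the surface. A
#' returning individual re-draws its origin among cells matching its
#' previous origin's plant-carbon value, with fresh year-to-year deuterium
#' jitter: carbon stays repeatable across years while deuterium varies. If
#' no cell falls within tolerance the tolerance is doubled with a warning.
#' With a zero hydrogen slope origins are drawn uniformly, independent of
#' blackness.
#'
#' @param roster roster data.frame from \code{\link{make_roster}}.
#' @param isoscapes list from \code{\link{make_isoscapes}} (element \code{h}
#'   uncalibrated precipitation surface, \code{c} plant surface).
#' @param config a \code{\link{sim_config}}.
#' @param params \code{\link{calibration_params}} used for the feather
#'   surface.
#' @return data.frame: roster columns plus \code{origin_cell} (linear cell
#'   index), \code{true_h} (calibrated feather deuterium at the origin) and
#'   \code{true_c_plant} (plant carbon at the origin).
#' @export
assign_true_origins <- function(roster, isoscapes, config,
                                params = calibration_params()) {
  stopifnot(inherits(config, "sim_config"))
  calib <- if (isoscapes$h$calibrated) isoscapes$h else
    calibrate_h(isoscapes$h, params)
  hv <- as.vector(calib$values)
  cv <- as.vector(isoscapes$c$values)
  ok <- which(!is.na(hv) & !is.na(cv))
  if (length(ok) < 1) {
    stop("isoscape has no usable cells; cannot place origins")
  }
  if (length(ok) < 10) {
    warning("isoscape has fewer than 10 usable cells; origins will be ",
            "heavily constrained")
  }
  betaH <- config$phenotype_betas$hydrogen
  center_h <- mean(range(hv[ok]))
  halfw <- config$origin_params$target_halfwidth
  # rescale the raw inverse span (100 / |betaH| permil across the blackness
  # range) into [-halfw, +halfw] about the surface center
  target_of <- function(latent) {
    if (betaH == 0) return(rep(center_h, length(latent)))
    center_h + (latent - 50) / betaH * (halfw * abs(betaH) / 50)
  }
  pick_within <- function(vals, target, tol) {
    repeat {
      cand <- ok[abs(vals[ok] - target) <= tol]
      if (length(cand)) return(cand)
      tol <- tol * 2
      warning(sprintf(
        "no cell within tolerance of target %.1f; widening to %.1f",
        target, tol))
    }
  }
  with_stage_seed(config$seed, "origins", {
    n <- nrow(roster)
    origin <- integer(n)
    roster <- roster[order(roster$year), , drop = FALSE]
    first_origin <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(n)) {
      id <- roster$id[i]
      tgt <- target_of(roster$latent_blackness[i])
      if (!exists(id, envir = first_origin, inherits = FALSE)) {
        if (betaH == 0) {
          cell <- ok[sample.int(length(ok), 1)]
        } else {
          cand <- pick_within(hv, tgt, config$origin_params$tol_h)
          cell <- cand[sample.int(length(cand), 1)]
        }
        assign(id, cell, envir = first_origin)
      } else {
        prev_c <- cv[get(id, envir = first_origin)]
        cand <- pick_within(cv, prev_c, config$origin_params$tol_c)
        want_h <- tgt + stats::rnorm(1, 0, config$origin_params$repeat_sd_h)
        cell <- cand[which.min(abs(hv[cand] - want_h))]
      }
      origin[i] <- cell
    }
    out <- roster
    out$origin_cell <- origin
    out$true_h <- hv[origin]
    out$true_c_plant <- cv[origin]
    attr(out, "center_h") <- center_h
    rownames(out) <- NULL
    out
  })
}

#' Complete the feather-sample table
#'
#' Observed isotope values are the transformed isoscape values at each true
#' origin plus noise: deuterium adds the calibration residual and the
#' measurement error; carbon adds the diet-to-consumer discrimination and
#' measurement error; nitrogen is an aspatial individual baseline plus
#' within-individual and measurement noise (it is excluded from spatial
#' assignment). Observed blackness is then drawn from the planted phenotype
#' model: mean = intercept + hydrogen slope x observed deuterium + age
#' effect, with an individual (ring) effect and residual drawn from
#' mean-zero, variance-exact bounded (scaled beta) distributions so the
#' percentage scale never truncates them, and finally snapped to the
#' blackness grid. With all SDs zero the isotope values equal the
#' transformed surface values exactly.
#'
#' @param origins data.frame from \code{\link{assign_true_origins}}.
#' @param config a \code{\link{sim_config}}.
#' @param params \code{\link{calibration_params}}.
#' @return data.frame with columns \code{id, year, age, blackness_pct,
#'   d13C, d15N, d2H} plus the true-state columns of \code{origins}.
#' @export
sample_feather_values <- function(origins, config,
                                  params = calibration_params()) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(origins)
  pb <- config$phenotype_betas
  with_stage_seed(config$seed, "feathers", {
    d2H <- origins$true_h +
      stats::rnorm(n, 0, config$sigma_resid_cal) +
      stats::rnorm(n, 0, config$sigma_meas[["H"]])
    d13C <- origins$true_c_plant + params$c_discrimination +
      stats::rnorm(n, 0, config$sigma_meas[["C"]])
    ids <- unique(origins$id)
    n15_base <- stats::setNames(
      stats::rnorm(length(ids), config$n15_params$mean,
                   config$n15_params$between_sd), ids)
    d15N <- n15_base[origins$id] +
      stats::rnorm(n, 0, config$n15_params$within_sd) +
      stats::rnorm(n, 0, config$sigma_meas[["N"]])
    center_h <- attr(origins, "center_h")
    if (is.null(center_h)) center_h <- mean(d2H)
    c_center <- mean(range(origins$true_c_plant)) + params$c_discrimination
    young <- as.numeric(origins$age == "young")
    b0 <- 50 - pb$hydrogen * center_h - pb$carbon * c_center -
      pb$nitrogen * config$n15_params$mean - pb$age_young * 0.5
    mu <- b0 + pb$hydrogen * d2H + pb$carbon * d13C + pb$nitrogen * d15N +
      pb$age_young * young
    mu <- pmin(pmax(mu, 4), 96)  # keep residual support workable
    # individual (ring) effect: support respects every record of the id
    L <- stats::ave(mu, origins$id, FUN = min)
    H <- stats::ave(100 - mu, origins$id, FUN = min)
    lo_b <- pmax(-(L - 3.5), -40)
    hi_b <- pmin(H - 3.5, 40)
    b_id <- stats::setNames(numeric(length(ids)), ids)
    first <- !duplicated(origins$id)
    if (pb$id_var > 0) {
      b_id[origins$id[first]] <-
        rbeta_bounded(sum(first), pb$id_var, lo_b[first], hi_b[first])
    }
    b <- as.numeric(b_id[origins$id])
    eps <- if (pb$resid_var > 0) {
      rbeta_bounded(n, pb$resid_var, -(mu + b), 100 - (mu + b))
    } else 0
    raw <- mu + b + eps
    grid <- sort(config$blackness_grid)
    snap <- vapply(raw, function(x) grid[which.min(abs(grid - x))],
                   numeric(1))
    out <- origins
    out$blackness_pct <- snap
    out$d13C <- as.numeric(d13C)
    out$d15N <- as.numeric(d15N)
    out$d2H <- as.numeric(d2H)
    attr(out, "center_h") <- center_h
    attr(out, "mu") <- mu
    out
  })
}

#' Generate the per-year winter environmental indices
#'
#' One row per winter: the station-based winter (December-March) NAO index,
#' mean February-March NDVI over the wintering box, and mean monthly
#' rainfall. Rainfall is linearly and negatively coupled to NAO (positive
#' NAO = drier West African winters) plus residual noise; NDVI is positively
#' coupled to rainfall and clamped to its physical range [-1, 1]. With the
#' rainfall residual SD set to zero the NAO-rain correlation is exactly -1.
#'
#' @param config a \code{\link{sim_config}}.
#' @param years integer years to generate; defaults to the roster years plus
#'   the following year (the winter preceding the last potential return).
#' @return data.frame with columns \code{year, nao, ndvi, rain_mm}.
#' @export
make_env_series <- function(config, years = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(years)) {
    ry <- as.integer(names(config$year_counts))
    years <- seq(min(ry), max(ry) + 1L)
  }
  ep <- config$env_params
  with_stage_seed(config$seed, "env", {
    n <- length(years)
    nao <- stats::rnorm(n, ep$nao_mean, ep$nao_sd)
    rain <- ep$rain_intercept + ep$rain_slope * nao +
      stats::rnorm(n, 0, ep$rain_resid_sd)
    rain <- pmax(rain, 0)
    rain_sd <- sqrt((ep$rain_slope * ep$nao_sd)^2 + ep$rain_resid_sd^2)
    z_rain <- if (rain_sd > 0) {
      (rain - (ep$rain_intercept + ep$rain_slope * ep$nao_mean)) / rain_sd
    } else 0
    ndvi <- ep$ndvi_mean +
      ep$ndvi_sd * (0.6 * z_rain + 0.8 * stats::rnorm(n))
    ndvi <- pmin(pmax(ndvi, -1), 1)
    data.frame(year = as.integer(years), nao = nao, ndvi = ndvi,
               rain_mm = rain)
  })
}

#' Simulate return outcomes from the planted hazard model
#'
#' For each feather record, the log-hazard of returning the next spring is a
#' linear predictor of centered covariate products: deuterium x NAO,
#' deuterium x rainfall, and blackness x NAO interactions (defaults the
#' planted study effects), an age-at-first-capture effect and an optional
#' individual gaussian frailty. Returns are drawn Bernoulli with
#' p = 1 - exp(-exp(baseline + eta)), the complementary log-log link, so the
#' generator is a discrete-time proportional-hazards model. The relevant
#' winter for a bird sampled in year t is the winter ending in year t + 1.
#'
#' @param samples completed sample table from
#'   \code{\link{sample_feather_values}}.
#' @param env environmental index table from \code{\link{make_env_series}}.
#' @param config a \code{\link{sim_config}}.
#' @return data.frame of return records: \code{id, year, age_first,
#'   blackness_pct, d13C, d15N, d2H, nao, ndvi, rain_mm, returned}, plus the
#'   true return probability \code{p_true} for diagnostics.
#' @export
simulate_returns <- function(samples, env, config) {
  stopifnot(inherits(config, "sim_config"))
  check_columns(samples, c("id", "year", "age", "blackness_pct", "d2H"),
                "sample table")
  check_columns(env, c("year", "nao", "ndvi", "rain_mm"), "env table")
  winter_year <- samples$year + 1L
  miss <- setdiff(unique(winter_year), env$year)
  if (length(miss)) {
    stop("no environmental record for winter year ",
         paste(sort(miss), collapse = ", "))
  }
  idx <- match(winter_year, env$year)
  hb <- config$hazard_betas
  ep <- config$env_params
  center_h <- attr(samples, "center_h")
  if (is.null(center_h)) center_h <- mean(samples$d2H)
  rain_center <- ep$rain_intercept + ep$rain_slope * ep$nao_mean
  # age at first capture, taken from each individual's first record
  ord <- order(samples$year)
  age_first_map <- tapply(samples$age[ord], samples$id[ord], `[`, 1)
  age_first <- as.character(age_first_map[samples$id])
  young1 <- as.numeric(age_first == "young")
  nao <- env$nao[idx]
  rain <- env$rain_mm[idx]
  eta <- hb$h_nao * (samples$d2H - center_h) * (nao - ep$nao_mean) +
    hb$h_rain * (samples$d2H - center_h) * (rain - rain_center) +
    hb$black_nao * (samples$blackness_pct - 50) * (nao - ep$nao_mean) +
    hb$age_young * (young1 - 0.5)
  with_stage_seed(config$seed, "returns", {
    ids <- unique(samples$id)
    frail <- stats::setNames(
      stats::rnorm(length(ids), 0, hb$frailty_sd), ids)
    p <- 1 - exp(-exp(hb$baseline + eta + frail[samples$id]))
    returned <- stats::rbinom(nrow(samples), 1, p)
    data.frame(id = samples$id, year = samples$year, age_first = age_first,
               blackness_pct = samples$blackness_pct, d13C = samples$d13C,
               d15N = samples$d15N, d2H = samples$d2H,
               nao = nao, ndvi = env$ndvi[idx], rain_mm = rain,
               returned = returned, p_true = as.numeric(p),
               stringsAsFactors = FALSE)
  })
}

#' Run the full generator
#'
#' Convenience wrapper chaining isoscapes, roster, origin placement, feather
#' values, environmental indices and return outcomes under one seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param params \code{\link{calibration_params}}.
#' @return list of class \code{"winterscape_sim"} with elements
#'   \code{config, isoscapes, roster, samples, env, returns}.
#' @export
simulate_dataset <- function(config = sim_config(),
                             params = calibration_params()) {
  iso <- make_isoscapes(config)
  ros <- make_roster(config)
  org <- assign_true_origins(ros$roster, iso, config, params)
  smp <- sample_feather_values(org, config, params)
  env <- make_env_series(config)
  ret <- simulate_returns(smp, env, config)
  structure(list(config = config, isoscapes = iso, roster = ros$roster,
                 n_repeat = ros$n_repeat, samples = smp, env = env,
                 returns = ret),
            class = "winterscape_sim")
}

#' @export
print.winterscape_sim <- function(x, ...) {
  cat(sprintf(
    "winterscape_sim: %d records, %d individuals (%d repeated), %d winters\n",
    nrow(x$samples), length(unique(x$samples$id)), x$n_repeat, nrow(x$env)))
  cat(sprintf("  return rate: %.3f\n", mean(x$returns$returned)))
  invisible(x)
}
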