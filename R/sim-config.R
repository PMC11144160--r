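# Configuration of the synthetic-data generator.

#' Default per-year male sample counts
#'
#' Eight breeding seasons with roughly 30 sampled males each (28-31 per
#' year), totalling 240 feather records.
#'
#' @return named integer vector (names are calendar years).
#' @export
default_year_counts <- function() {
  c("2007" = 30L, "2008" = 30L, "2009" = 31L, "2010" = 31L,
    "2011" = 31L, "2012" = 29L, "2013" = 28L, "2014" = 30L)
}

#' Synthetic-study configuration
#'
#' Bundles every tunable of the generator: the study roster, the isoscape
#' geometry, measurement and calibration noise, the planted phenotype and
#' return (hazard) models, and the winter environmental indices. Defaults
#' encode the study conditions the package is validated against: the
#' per-year roster above; measurement errors of 2 permil (deuterium) and
#' 0.1 permil (carbon, nitrogen); a feather-calibration residual of 12
#' permil; a blackness model with a hydrogen slope of -0.50 percent per
#' permil, an age (young) effect of -19.30 percent, individual (ring)
#' variance 365.8 and residual variance 314.8; and hazard interactions
#' d2H x NAO = -0.04, d2H x rain = 0.004, blackness x NAO = 0.007 on the
#' complementary log-log scale.
#'
#' @param seed integer root seed; every stage derives its own substream.
#' @param grid_shape integer c(rows, cols) of the isoscape grid.
#' @param extent c(xmin, xmax, ymin, ymax) in degrees (west longitudes
#'   negative).
#' @param year_counts named integer vector of males sampled per year.
#' @param repeat_fraction proportion of individuals sampled in more than one
#'   (consecutive) year; the default yields 31 repeated individuals out of
#'   209 on the default roster.
#' @param sigma_meas named measurement SDs, per mil: H, C, N.
#' @param sigma_resid_cal deuterium calibration residual SD, per mil.
#' @param blackness_grid allowed blackness values (percent).
#' @param phenotype_betas list: \code{hydrogen}, \code{carbon},
#'   \code{nitrogen} (percent per permil), \code{age_young} (percent),
#'   \code{id_var}, \code{resid_var} (percent squared).
#' @param hazard_betas list: interaction coefficients \code{h_nao},
#'   \code{h_rain}, \code{black_nao}, plus \code{age_young},
#'   \code{baseline} (complementary log-log intercept) and
#'   \code{frailty_sd} (individual log-hazard SD).
#' @param env_params list: \code{nao_mean}, \code{nao_sd}, \code{ndvi_mean},
#'   \code{ndvi_sd}, \code{rain_intercept}, \code{rain_slope} (mm per NAO
#'   unit, negative: positive NAO means drier winters),
#'   \code{rain_resid_sd}.
#' @param isoscape_params list: \code{h_range} and \code{c_range} (planar
#'   gradient endpoints, per mil; deuterium runs west to east, carbon south
#'   to north), \code{noise_amp} (named H/C, per mil), \code{noise_scale}
#'   (cells), \code{mask_fraction}.
#' @param origin_params list: \code{target_halfwidth} (per mil; half-range
#'   of feather-deuterium origin targets across the blackness gradient),
#'   \code{tol_h}, \code{tol_c} (cell-matching tolerances, per mil),
#'   \code{repeat_sd_h} (year-to-year deuterium jitter for returning
#'   individuals, per mil).
#' @param n15_params list: \code{mean}, \code{between_sd}, \code{within_sd}
#'   (per mil) for the aspatial nitrogen baseline.
#' @param age_young_prob probability a newly captured individual is in its
#'   second calendar year (young).
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       grid_shape = c(40L, 40L),
                       extent = c(-20, 0, 0, 20),
                       year_counts = default_year_counts(),
                       repeat_fraction = 31 / 209,
                       sigma_meas = c(H = 2.0, C = 0.1, N = 0.1),
                       sigma_resid_cal = 12.0,
                       blackness_grid = seq(0, 100, by = 5),
                       phenotype_betas = list(
                         hydrogen = -0.50, carbon = 0, nitrogen = 0,
                         age_young = -19.30,
                         id_var = 365.8, resid_var = 314.8),
                       hazard_betas = list(
                         h_nao = -0.04, h_rain = 0.004, black_nao = 0.007,
                         age_young = -0.2,
                         baseline = log(-log(1 - 0.3)),
                         frailty_sd = 0),
                       env_params = list(
                         nao_mean = -0.31, nao_sd = 1.87,
                         ndvi_mean = 0.45, ndvi_sd = 0.08,
                         rain_intercept = 55.3, rain_slope = -5.7,
                         rain_resid_sd = 4),
                       isoscape_params = list(
                         h_range = c(-60, -10), c_range = c(-28, -13),
                         noise_amp = c(H = 1.5, C = 0.4),
                         noise_scale = 3, mask_fraction = 0.05),
                       origin_params = list(
                         target_halfwidth = 24,
                         tol_h = 3, tol_c = 1.0, repeat_sd_h = 10),
                       n15_params = list(
                         mean = 8.0, between_sd = 1.0, within_sd = 0.5),
                       age_young_prob = 0.5) {
  cfg <- list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
              extent = as.numeric(extent), year_counts = year_counts,
              repeat_fraction = repeat_fraction, sigma_meas = sigma_meas,
              sigma_resid_cal = sigma_resid_cal,
              blackness_grid = blackness_grid,
              phenotype_betas = phenotype_betas,
              hazard_betas = hazard_betas, env_params = env_params,
              isoscape_params = isoscape_params,
              origin_params = origin_params, n15_params = n15_params,
              age_young_prob = age_young_prob)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$grid_shape) != 2 || any(cfg$grid_shape < 2)) {
    stop("grid_shape must be c(rows, cols) with both at least 2")
  }
  if (cfg$extent[2] <= cfg$extent[1] || cfg$extent[4] <= cfg$extent[3]) {
    stop("degenerate extent: xmax must exceed xmin and ymax exceed ymin")
  }
  if (is.null(names(cfg$year_counts)) || any(cfg$year_counts < 1)) {
    stop("year_counts must be a named (year) vector of positive counts")
  }
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction > 1) {
    stop("repeat_fraction must lie in [0, 1]")
  }
  if (any(cfg$sigma_meas < 0) || cfg$sigma_resid_cal < 0) {
    stop("measurement and calibration SDs must be non-negative")
  }
  if (any(cfg$blackness_grid < 0 | cfg$blackness_grid > 100)) {
    stop("blackness_grid values must lie in [0, 100]")
  }
  with(cfg$phenotype_betas, {
    if (id_var < 0 || resid_var < 0) stop("variance components must be >= 0")
  })
  if (cfg$hazard_betas$frailty_sd < 0) stop("frailty_sd must be >= 0")
  ip <- cfg$isoscape_params
  if (ip$mask_fraction < 0 || ip$mask_fraction >= 1) {
    stop("mask_fraction must lie in [0, 1)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", sum(x$year_counts), "records over",
      length(x$year_counts), "years; grid",
      paste(x$grid_shape, collapse = " x "),
      "; seed", x$seed, "\n")
  invisible(x)
}
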