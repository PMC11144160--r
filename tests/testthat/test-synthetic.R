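test_that("the generator is deterministic given the configuration seed", {
  s1 <- simulate_dataset(small_config(seed = 42))
  s2 <- simulate_dataset(small_config(seed = 42))
  expect_identical(s1$isoscapes$h$values, s2$isoscapes$h$values)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$env, s2$env)
  expect_identical(s1$returns, s2$returns)
  s3 <- simulate_dataset(small_config(seed = 43))
  expect_false(identical(s1$samples$d2H, s3$samples$d2H))
})

test_that("noiseless isoscapes equal the configured planar gradients", {
  cfg <- small_config(isoscape_params = list(
    h_range = c(-60, -10), c_range = c(-28, -13),
    noise_amp = c(H = 0, C = 0), noise_scale = 3, mask_fraction = 0))
  iso <- make_isoscapes(cfg)
  expect_equal(min(iso$h$values), -60)
  expect_equal(max(iso$h$values), -10)
  # pure west-east gradient: all rows identical, first column = -60
  expect_equal(iso$h$values[1, ], iso$h$values[20, ])
  expect_equal(unique(iso$h$values[, 1]), -60)
  # carbon runs south (row 20) to north (row 1)
  expect_equal(unique(iso$c$values[20, ]), -28)
  expect_equal(unique(iso$c$values[1, ]), -13)
  # exact plane at interior cells too (linear in normalized position)
  expect_equal(iso$h$values[5, 11], -60 + (11 - 1) / 19 * 50)
})

test_that("masking removes the configured fraction of cells in both surfaces", {
  cfg <- small_config(isoscape_params = list(
    h_range = c(-60, -10), c_range = c(-28, -13),
    noise_amp = c(H = 1.5, C = 0.4), noise_scale = 3, mask_fraction = 0.1))
  iso <- make_isoscapes(cfg)
  expect_equal(sum(is.na(iso$h$values)) / 400, 0.1, tolerance = 0.02)
  expect_identical(is.na(iso$h$values), is.na(iso$c$values))
})

test_that("the default roster matches the study sampling design", {
  cfg <- sim_config()
  ros <- make_roster(cfg)
  expect_equal(nrow(ros$roster), 240)
  expect_equal(as.vector(table(ros$roster$year)),
               as.vector(default_year_counts()))
  expect_equal(ros$n_repeat, 31)
  expect_equal(length(unique(ros$roster$id)), 209)
  # repeats are in consecutive years with age advancing to old
  reps <- names(which(table(ros$roster$id) > 1))
  for (id in reps[1:5]) {
    g <- ros$roster[ros$roster$id == id, ]
    g <- g[order(g$year), ]
    expect_equal(diff(g$year), 1)
    expect_equal(g$age[2], "old")
  }
  expect_true(all(ros$roster$latent_blackness %in% cfg$blackness_grid))
})

test_that("repeat_fraction 0 yields unique individuals", {
  ros <- make_roster(small_config(repeat_fraction = 0))
  expect_equal(ros$n_repeat, 0)
  expect_equal(length(unique(ros$roster$id)), nrow(ros$roster))
  expect_error(small_config(repeat_fraction = 1.2), "repeat_fraction")
})

test_that("origin placement follows the inverted blackness-deuterium line", {
  cfg <- sim_config(
    grid_shape = c(40L, 40L),
    year_counts = c("2007" = 2L), repeat_fraction = 0,
    isoscape_params = list(h_range = c(-60, -10), c_range = c(-28, -13),
                           noise_amp = c(H = 0, C = 0), noise_scale = 3,
                           mask_fraction = 0),
    origin_params = list(target_halfwidth = 24, tol_h = 1, tol_c = 1,
                         repeat_sd_h = 0))
  iso <- make_isoscapes(cfg)
  ros <- make_roster(cfg)
  ros$roster$latent_blackness <- c(0, 100)
  org <- assign_true_origins(ros$roster, iso, cfg)
  black <- org$true_h[org$latent_blackness == 100]
  brown <- org$true_h[org$latent_blackness == 0]
  expect_lte(black, brown)  # blacker individuals sit at lower deuterium
  # inverse span rescaled into the configured half-width
  expect_equal(brown - black, 48, tolerance = 2)
})

test_that("a zero hydrogen slope decouples origins from blackness", {
  cfg <- sim_config(
    year_counts = c("2007" = 1000L), repeat_fraction = 0,
    phenotype_betas = list(hydrogen = 0, carbon = 0, nitrogen = 0,
                           age_young = -19.3, id_var = 365.8,
                           resid_var = 314.8))
  iso <- make_isoscapes(cfg)
  ros <- make_roster(cfg)
  org <- assign_true_origins(ros$roster, iso, cfg)
  expect_lt(abs(cor(org$latent_blackness, org$true_h)), 0.08)
})

test_that("origins collapse onto the only usable cell", {
  cfg <- small_config(year_counts = c("2007" = 5L))
  vals_h <- matrix(NA_real_, 20, 20); vals_h[7, 9] <- -40
  vals_c <- matrix(NA_real_, 20, 20); vals_c[7, 9] <- -20
  iso <- list(h = isoscape(vals_h, cfg$extent, isotope = "d2H"),
              c = isoscape(vals_c, cfg$extent, isotope = "d13C"))
  ros <- make_roster(cfg)
  org <- suppressWarnings(assign_true_origins(ros$roster, iso, cfg))
  expect_true(all(org$origin_cell == which(!is.na(as.vector(vals_h)))))
})

test_that("noiseless feather values equal transformed surface values", {
  cfg <- small_config(
    sigma_meas = c(H = 0, C = 0, N = 0), sigma_resid_cal = 0,
    n15_params = list(mean = 8, between_sd = 1, within_sd = 0))
  iso <- make_isoscapes(cfg)
  ros <- make_roster(cfg)
  org <- assign_true_origins(ros$roster, iso, cfg)
  smp <- sample_feather_values(org, cfg)
  expect_equal(smp$d2H, smp$true_h)
  expect_equal(smp$d13C, smp$true_c_plant + 2)
  # nitrogen is the individual baseline: exactly repeatable within id
  reps <- names(which(table(smp$id) > 1))
  for (id in reps) {
    expect_equal(diff(smp$d15N[smp$id == id]), 0)
  }
})

test_that("feather deuterium noise follows variance addition", {
  cfg <- sim_config(year_counts = c("2007" = 10000L), repeat_fraction = 0)
  iso <- make_isoscapes(cfg)
  ros <- make_roster(cfg)
  org <- assign_true_origins(ros$roster, iso, cfg)
  smp <- sample_feather_values(org, cfg)
  sd_obs <- sd(smp$d2H - smp$true_h)
  expect_equal(sd_obs, sqrt(2^2 + 12^2), tolerance = 0.03 * sqrt(148))
})

test_that("observed blackness stays on the grid and spans the range", {
  sim <- simulate_dataset(sim_config(seed = 5))
  expect_true(all(sim$samples$blackness_pct %in% sim$config$blackness_grid))
  expect_gt(diff(range(sim$samples$blackness_pct)), 80)
})

test_that("environmental series has the configured structure", {
  cfg <- sim_config(seed = 8)
  env <- make_env_series(cfg)
  expect_equal(env$year, 2007:2015)
  expect_true(all(env$ndvi >= -1 & env$ndvi <= 1))
  expect_true(all(env$rain_mm >= 0))
  expect_lt(cor(env$nao, env$rain_mm), 0)
  expect_identical(env, make_env_series(cfg))
  # noiseless linear link: correlation exactly -1
  cfg0 <- sim_config(env_params = list(
    nao_mean = -0.31, nao_sd = 1.87, ndvi_mean = 0.45, ndvi_sd = 0.08,
    rain_intercept = 55.3, rain_slope = -5.7, rain_resid_sd = 0))
  env0 <- make_env_series(cfg0)
  expect_equal(cor(env0$nao, env0$rain_mm), -1)
})

test_that("null return model gives the baseline rate", {
  cfg <- sim_config(
    year_counts = c("2007" = 10000L), repeat_fraction = 0,
    hazard_betas = list(h_nao = 0, h_rain = 0, black_nao = 0,
                        age_young = 0, baseline = log(-log(0.5)),
                        frailty_sd = 0))
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$returns$p_true == 0.5))
  expect_equal(mean(sim$returns$returned), 0.5,
               tolerance = 3 * 0.5 / sqrt(10000))
})

test_that("a negative deuterium-NAO interaction favours low-d2H birds in high-NAO winters", {
  yc <- setNames(rep(250L, 8), 2007:2014)
  cfg <- sim_config(
    seed = 3, year_counts = yc, repeat_fraction = 0,
    hazard_betas = list(h_nao = -0.04, h_rain = 0, black_nao = 0,
                        age_young = 0, baseline = log(-log(0.7)),
                        frailty_sd = 0))
  sim <- simulate_dataset(cfg)
  ret <- sim$returns
  hi <- ret$nao > quantile(ret$nao, 0.5)
  # within a high-NAO winter the true return probability decreases in d2H
  expect_lt(cor(ret$d2H[hi], ret$p_true[hi]), 0)
  expect_gt(cor(ret$d2H[!hi], ret$p_true[!hi]), 0)
})

test_that("a missing winter in the env table is reported by year", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg)
  env <- sim$env[sim$env$year != 2010, ]
  expect_error(simulate_returns(sim$samples, env, cfg), "2010")
})
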