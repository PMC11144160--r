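test_that("posterior surfaces normalize to one and respect masks", {
  set.seed(1)
  for (k in 1:5) {
    v_h <- matrix(rnorm(48, -50, 15), 6, 8)
    v_c <- matrix(rnorm(48, -22, 3), 6, 8)
    v_h[sample(48, 5)] <- NA
    v_c[is.na(v_h)] <- NA
    p <- posterior_surface(-55, -21, mk_iso(v_h), mk_iso(v_c, sigma = 1.5),
                           sample_id = "s")
    expect_equal(sum(p$prob, na.rm = TRUE), 1, tolerance = 1e-9)
    expect_identical(is.na(p$prob), is.na(v_h))
    expect_true(all(p$prob >= 0, na.rm = TRUE))
  }
})

test_that("degenerate posterior cases behave analytically", {
  # single unmasked cell gets everything
  v <- matrix(NA_real_, 3, 3); v[2, 2] <- -40
  c1 <- v; c1[2, 2] <- -20
  p <- posterior_surface(-70, -25, mk_iso(v), mk_iso(c1, sigma = 1.5))
  expect_equal(p$prob[2, 2], 1)
  # spatially uniform surfaces give the uniform posterior
  u_h <- mk_iso(matrix(-50, 4, 5))
  u_c <- mk_iso(matrix(-22, 4, 5), sigma = 1.5)
  p <- posterior_surface(-61, -20, u_h, u_c)
  expect_equal(as.vector(p$prob), rep(1 / 20, 20))
})

test_that("two-cell deuterium-only posterior matches the direct computation", {
  v <- matrix(c(-60, -20), 1, 2)
  p <- posterior_surface(-60, NULL, mk_iso(v, sigma = 12), NULL)
  d <- exp(-((-60 + 20) / 12)^2 / 2)  # relative density of the far cell
  expect_equal(as.vector(p$prob), c(1, d) / (1 + d), tolerance = 1e-12)
  # frozen values from the brute-force computation
  expect_equal(as.vector(p$prob), c(0.9961489676, 0.0038510324),
               tolerance = 1e-7)
})

test_that("posterior and odds region agree with the brute-force oracle", {
  set.seed(7)
  for (k in 1:4) {
    nr <- sample(8:20, 1); nc <- sample(8:20, 1)
    v_h <- matrix(rnorm(nr * nc, -55, 18), nr, nc)
    v_c <- matrix(rnorm(nr * nc, -22, 3), nr, nc)
    drop <- sample(nr * nc, round(0.1 * nr * nc))
    v_h[drop] <- NA; v_c[drop] <- NA
    y_h <- rnorm(1, -55, 15); y_c <- rnorm(1, -22, 3)
    p <- posterior_surface(y_h, y_c, mk_iso(v_h), mk_iso(v_c, sigma = 1.5))
    oracle <- oracle_posterior(y_h, y_c, mk_iso(v_h),
                               mk_iso(v_c, sigma = 1.5), 12, 1.5)
    expect_lt(max(abs(p$prob - oracle), na.rm = TRUE), 1e-12)
    om <- odds_region(p)
    expect_identical(om$indicator, oracle_odds(oracle))
  }
})

test_that("the posterior is invariant to shared shifts and sigma rescaling", {
  v_h <- matrix(seq(-80, -20, length.out = 12), 3, 4)
  v_c <- matrix(seq(-28, -16, length.out = 12), 3, 4)
  p1 <- posterior_surface(-50, -22, mk_iso(v_h), mk_iso(v_c, sigma = 1.5))
  # shift both sample and surface by a constant
  p2 <- posterior_surface(-50 + 30, -22 + 5, mk_iso(v_h + 30),
                          mk_iso(v_c + 5, sigma = 1.5))
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
  # rescale both sigmas and all anomalies by the same factor
  p3 <- posterior_surface(-100, -44, mk_iso(2 * v_h, sigma = 24),
                          mk_iso(2 * v_c, sigma = 3))
  expect_equal(p1$prob, p3$prob, tolerance = 1e-12)
})

test_that("non-finite inputs and empty grids raise informative errors", {
  v <- matrix(-50, 2, 2)
  expect_error(posterior_surface(NaN, -22, mk_iso(v), mk_iso(v, sigma = 1.5),
                                 sample_id = "bird7"), "bird7")
  allna <- matrix(NA_real_, 2, 2)
  expect_error(posterior_surface(-50, -22, mk_iso(allna),
                                 mk_iso(allna, sigma = 1.5)), "masked")
})

test_that("odds region takes the smallest highest-probability set", {
  mk_p <- function(probs, nr = 1) {
    structure(list(prob = matrix(probs, nr), extent = c(0, length(probs), 0, 1),
                   sample_id = "t", sigma = c(H = 12, C = 1.5)),
              class = "prob_surface")
  }
  om <- odds_region(mk_p(c(0.7, 0.2, 0.1)))
  expect_equal(as.vector(om$indicator), c(1L, 0L, 0L))
  expect_equal(om$achieved_mass, 0.7)
  # uniform three-cell posterior: two cells reach 2/3 but the third ties
  om3 <- odds_region(mk_p(rep(1 / 3, 3)))
  expect_equal(as.vector(om3$indicator), c(1L, 1L, 1L))
  expect_equal(om3$achieved_mass, 1)
  expect_error(odds_region(mk_p(c(0.5, 0.5)), mass = 0), "mass")
  expect_error(odds_region(mk_p(c(0.5, 0.5)), mass = 1.4), "mass")
})

test_that("odds regions are minimal highest-density sets on random surfaces", {
  set.seed(11)
  for (k in 1:10) {
    n <- sample(20:80, 1)
    pr <- rexp(n); pr <- pr / sum(pr)
    p <- structure(list(prob = matrix(pr, 1), extent = c(0, n, 0, 1),
                        sample_id = "t", sigma = c(H = 12, C = 1.5)),
                   class = "prob_surface")
    om <- odds_region(p)
    inc <- om$indicator[1, ] == 1
    expect_gte(om$achieved_mass, 2 / 3 - 1e-12)
    # every excluded cell is no more probable than any included cell
    if (any(!inc)) expect_lte(max(pr[!inc]), min(pr[inc]) + 1e-15)
    # removing the smallest included cell drops below the mass threshold
    # (continuous draws, so ties have probability zero and the prefix is
    # exactly minimal)
    expect_lt(om$achieved_mass - min(pr[inc]), 2 / 3)
  }
})

test_that("blackness grouping uses the documented boundaries", {
  g <- group_by_blackness(c(10, 33, 66, 70, 0, 100, 32.9, 66.1))
  expect_equal(as.character(g),
               c("low", "moderate", "moderate", "high", "low", "high",
                 "low", "high"))
  g50 <- group_by_blackness(rep(50, 7))
  expect_equal(as.vector(table(g50)), c(0, 7, 0))
  g0 <- group_by_blackness(numeric(0))
  expect_equal(levels(g0), c("low", "moderate", "high"))
  expect_equal(length(g0), 0)
  expect_error(group_by_blackness(c(5, 105)), "0, 100")
})

test_that("count surfaces sum binary maps cell-wise", {
  mk_map <- function(ind) {
    structure(list(indicator = ind, extent = c(0, ncol(ind), 0, nrow(ind)),
                   achieved_mass = 0.7, n_cells = sum(ind, na.rm = TRUE),
                   sample_id = "t", mass = 2 / 3),
              class = "origin_map")
  }
  a <- matrix(c(1L, 0L, 1L, 1L, 0L, 0L), 2, 3)
  b <- matrix(c(1L, 1L, 1L, 1L, 0L, 1L), 2, 3)
  cs <- sum_origin_maps(list(mk_map(a), mk_map(b)), group = "low")
  expect_equal(cs$counts, a + b)
  expect_equal(sum(cs$counts == 2L), 3)  # overlap in exactly 3 cells
  expect_equal(cs$min_count, 0L)
  expect_equal(cs$max_count, 2L)
  # N copies of one map give counts 0 or N
  cs5 <- sum_origin_maps(rep(list(mk_map(a)), 5))
  expect_true(all(cs5$counts %in% c(0L, 5L)))
  # empty list with a template grid gives the zero surface
  cs0 <- sum_origin_maps(list(), template = mk_map(a))
  expect_true(all(cs0$counts == 0L))
  expect_equal(cs0$n, 0L)
  # misaligned grids are refused
  d <- matrix(c(1L, 0L), 1, 2)
  expect_error(sum_origin_maps(list(mk_map(a), mk_map(d))), "shared grid")
})

test_that("assign_all groups records and reports achieved masses", {
  sim <- simulate_dataset(small_config(seed = 2))
  hs <- calibrate_h(sim$isoscapes$h)
  cs <- discriminate_c(sim$isoscapes$c)
  al <- align_and_mask(list(hs, cs))
  res <- assign_all(sim$samples, al[[1]], al[[2]])
  expect_equal(nrow(res$summary), nrow(sim$samples))
  expect_true(all(res$summary$achieved_mass >= 2 / 3 - 1e-12))
  expect_equal(sum(vapply(res$count_surfaces, function(x) x$n, numeric(1))),
               nrow(sim$samples))
})

test_that("odds-region coverage responds to sigma misspecification", {
  cfg <- small_config(seed = 4)
  iso <- make_isoscapes(cfg)
  hs <- calibrate_h(iso$h)
  cs <- discriminate_c(iso$c)
  cov_ok <- coverage_calibration(200, hs, cs, sigma_true_h = sqrt(148),
                                 sigma_true_c = 0.5, seed = 9)
  cov_wide <- coverage_calibration(200, hs, cs, sigma_true_h = sqrt(148),
                                   sigma_true_c = 0.5,
                                   sigma_h = 10 * sqrt(148), sigma_c = 5,
                                   seed = 9)
  cov_narrow <- coverage_calibration(200, hs, cs, sigma_true_h = sqrt(148),
                                     sigma_true_c = 0.5,
                                     sigma_h = sqrt(148) / 10,
                                     sigma_c = 0.05, seed = 9)
  expect_gt(cov_ok$coverage, 0.55)
  expect_lt(cov_ok$coverage, 0.8)
  expect_gt(cov_wide$coverage, cov_narrow$coverage)
  expect_lt(cov_narrow$coverage, 2 / 3)
})
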