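# Phenotype statistics: repeatability, the blackness mixed model, the
# residual-dispersion check, the between-year change model, and exploratory
# isotope-environment associations.

# Uniform container for fitted-model output: a data.frame of fixed-effect
# rows plus metadata attributes.
model_fit_summary <- function(terms, estimate, se, statistic, df, p,
                              random = NULL, meta = list()) {
  out <- data.frame(term = terms, estimate = estimate, se = se,
                    statistic = statistic, df = df, p = p,
                    stringsAsFactors = FALSE)
  attr(out, "random") <- random
  attr(out, "meta") <- meta
  class(out) <- c("model_fit_summary", "data.frame")
  out
}

#' @export
print.model_fit_summary <- function(x, ...) {
  meta <- attr(x, "meta")
  if (!is.null(meta$model)) cat(meta$model, "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  rnd <- attr(x, "random")
  if (!is.null(rnd)) {
    cat("random effects (variance):",
        paste(sprintf("%s = %.3f", names(rnd), rnd), collapse = ", "), "\n")
  }
  if (isTRUE(meta$singular)) cat("note: singular fit\n")
  invisible(x)
}

#' Within-individual repeatability (intraclass correlation)
#'
#' Fits a gaussian random-intercept model by REML and reports
#' R = V_individual / (V_individual + V_residual), with a parametric
#' bootstrap confidence interval (refitting on data simulated from the
#' fitted model) and a likelihood-ratio test against zero individual
#' variance whose p-value is halved for the boundary.
#'
#' @param values numeric response vector.
#' @param id individual identifiers (same length).
#' @param n_boot number of parametric bootstrap resamples (default 1000; a
#'   value below 100 triggers a warning; 0 skips the bootstrap and returns
#'   an NA interval, useful when only the point estimate is needed).
#' @param ci_level confidence level, default 0.95.
#' @param seed integer seed for the bootstrap.
#' @return object of class \code{"repeatability"}: \code{R}, \code{ci},
#'   \code{p}, \code{n_id}, \code{n_obs}, \code{n_boot}.
#' @export
repeatability <- function(values, id, n_boot = 1000, ci_level = 0.95,
                          seed = 1L) {
  ok <- is.finite(values) & !is.na(id)
  values <- values[ok]
  id <- factor(id[ok])
  counts <- table(id)
  if (sum(counts >= 2) < 2) {
    stop("repeatability needs at least 2 individuals with repeated measures")
  }
  if (n_boot > 0 && n_boot < 100) {
    warning("n_boot below 100 gives unstable confidence intervals")
  }
  d <- data.frame(y = values, id = id)
  fit <- lme4::lmer(y ~ 1 + (1 | id), data = d, REML = TRUE)
  icc_of <- function(m) {
    vc <- lme4::VarCorr(m)
    v_id <- as.numeric(vc$id[1])
    v_res <- attr(vc, "sc")^2
    if (v_id + v_res == 0) return(0)
    v_id / (v_id + v_res)
  }
  R <- icc_of(fit)
  # likelihood-ratio test against V_id = 0, halved (boundary correction)
  null <- stats::lm(y ~ 1, data = d)
  lrt <- 2 * (stats::logLik(lme4::refitML(fit)) - stats::logLik(null))
  p <- 0.5 * stats::pchisq(as.numeric(lrt), df = 1, lower.tail = FALSE)
  if (n_boot > 0) {
    boot_R <- with_stage_seed(seed, "rpt_boot", {
      sims <- stats::simulate(fit, nsim = n_boot)
      vapply(seq_len(n_boot), function(b) {
        db <- d
        db$y <- sims[[b]]
        m <- suppressMessages(suppressWarnings(
          lme4::lmer(y ~ 1 + (1 | id), data = db, REML = TRUE)))
        icc_of(m)
      }, numeric(1))
    })
    a <- (1 - ci_level) / 2
    ci <- pmin(pmax(stats::quantile(boot_R, c(a, 1 - a), names = FALSE),
                    0), 1)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(R = R, ci = ci, p = p, n_id = nlevels(id),
                 n_obs = length(values), n_boot = n_boot,
                 ci_level = ci_level),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("repeatability R = %.3f (%.0f%% CI [%.2f, %.2f], p = %.3g)\n",
              x$R, 100 * x$ci_level, x$ci[1], x$ci[2], x$p))
  cat(sprintf("  %d individuals, %d observations, %d bootstrap resamples\n",
              x$n_id, x$n_obs, x$n_boot))
  invisible(x)
}

#' Mixed model of plumage blackness on feather isotopes and age
#'
#' REML fit of blackness ~ d2H + d13C + d15N + age + (1 | individual), with
#' age coded as a two-level factor with reference level old (so the
#' reported effect is for young birds). Degrees of freedom and standard
#' errors use the Kenward-Roger small-sample method when pbkrtest is
#' available, otherwise Satterthwaite; the method in use is recorded in the
#' output metadata. Year is deliberately not a term: the roster is built to
#' represent the full coloration range every year, so year explains no
#' blackness variance by design.
#'
#' @param samples data.frame with columns \code{blackness_pct, d2H, d13C,
#'   d15N, age, id}.
#' @return a \code{model_fit_summary} with one row per fixed effect,
#'   random-effect variances and fit metadata (including a singular-fit
#'   flag).
#' @export
fit_blackness_lmm <- function(samples) {
  check_columns(samples,
                c("blackness_pct", "d2H", "d13C", "d15N", "age", "id"),
                "sample table")
  if (length(unique(samples$id)) < 10) {
    stop("need at least 10 individuals to fit the blackness mixed model")
  }
  d <- data.frame(blackness = samples$blackness_pct, d2H = samples$d2H,
                  d13C = samples$d13C, d15N = samples$d15N,
                  age = factor(samples$age, levels = c("old", "young")),
                  id = factor(samples$id))
  fit <- lmerTest::lmer(
    blackness ~ d2H + d13C + d15N + age + (1 | id), data = d, REML = TRUE)
  ddf <- if (requireNamespace("pbkrtest", quietly = TRUE)) {
    "Kenward-Roger"
  } else "Satterthwaite"
  cf <- stats::coef(summary(fit, ddf = ddf))
  vc <- lme4::VarCorr(fit)
  model_fit_summary(
    terms = rownames(cf), estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"], statistic = cf[, "t value"],
    df = cf[, "df"], p = cf[, "Pr(>|t|)"],
    random = c(id = as.numeric(vc$id[1]),
               residual = attr(vc, "sc")^2),
    meta = list(model = "blackness ~ d2H + d13C + d15N + age + (1|id)",
                method = "REML", ddf = ddf,
                n_obs = nrow(d), n_groups = nlevels(d$id),
                singular = lme4::isSingular(fit)))
}

#' Does deuterium dispersion change along the blackness gradient?
#'
#' Two-stage check for heteroscedasticity: regress feather deuterium on
#' blackness, then regress the absolute residuals of that model on
#' blackness again. A positive stage-two slope indicates more variable
#' deuterium (more variable winter-habitat rainfall) among one end of the
#' coloration gradient.
#'
#' @param samples data.frame with columns \code{d2H, blackness_pct}.
#' @return a \code{model_fit_summary} for the stage-two regression.
#' @export
residual_dispersion_vs_blackness <- function(samples) {
  check_columns(samples, c("d2H", "blackness_pct"), "sample table")
  ok <- is.finite(samples$d2H) & is.finite(samples$blackness_pct)
  if (sum(ok) < 3) stop("need at least 3 complete observations")
  d <- samples[ok, ]
  stage1 <- stats::lm(d2H ~ blackness_pct, data = d)
  absres <- abs(stats::residuals(stage1))
  if (all(absres == 0)) {
    return(model_fit_summary(
      terms = "blackness_pct", estimate = 0, se = NA_real_,
      statistic = NA_real_, df = NA_real_, p = NA_real_,
      meta = list(model = "|resid(d2H ~ blackness)| ~ blackness",
                  note = "all residuals zero")))
  }
  stage2 <- stats::lm(absres ~ d$blackness_pct)
  cf <- stats::coef(summary(stage2))
  model_fit_summary(
    terms = "blackness_pct", estimate = cf[2, 1], se = cf[2, 2],
    statistic = cf[2, 3], df = stage2$df.residual, p = cf[2, 4],
    meta = list(model = "|resid(d2H ~ blackness)| ~ blackness",
                n_obs = nrow(d)))
}

#' Between-year change in blackness versus change in deuterium
#'
#' For individuals sampled in successive years, regresses the within-
#' individual change in blackness on the change in feather deuterium,
#' controlling for the age class at the first capture of each pair (the
#' young-to-old transition carries the age-related darkening).
#'
#' @param samples data.frame with columns \code{id, year, age,
#'   blackness_pct, d2H}.
#' @return a \code{model_fit_summary} for the change regression.
#' @export
between_year_change_model <- function(samples) {
  check_columns(samples, c("id", "year", "age", "blackness_pct", "d2H"),
                "sample table")
  s <- samples[order(samples$id, samples$year), ]
  pairs <- do.call(rbind, lapply(split(s, s$id), function(g) {
    if (nrow(g) < 2) return(NULL)
    i <- seq_len(nrow(g) - 1)
    data.frame(d_black = diff(g$blackness_pct), d_d2H = diff(g$d2H),
               age_first = g$age[i], stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("no individuals with repeated yearly records")
  }
  if (nrow(pairs) < 4) {
    stop("only ", nrow(pairs),
         " repeat pair(s): insufficient degrees of freedom for the change model")
  }
  pairs$age_first <- factor(pairs$age_first, levels = c("old", "young"))
  fit <- stats::lm(d_black ~ d_d2H + age_first, data = pairs)
  cf <- stats::coef(summary(fit))
  model_fit_summary(
    terms = rownames(cf), estimate = cf[, 1], se = cf[, 2],
    statistic = cf[, 3], df = fit$df.residual, p = cf[, 4],
    meta = list(model = "d_blackness ~ d_d2H + age_first",
                n_pairs = nrow(pairs)))
}

#' Exploratory yearly isotope-environment associations
#'
#' For each isotope and each environmental index, regresses the yearly mean
#' feather isotope value on the index for the same winter. One point per
#' year; clearly exploratory plumbing connecting local (isotopic) to
#' general (index) winter conditions.
#'
#' @param samples data.frame with \code{year, d2H, d13C, d15N}.
#' @param env data.frame with \code{year, nao, ndvi, rain_mm}.
#' @return data.frame: one row per isotope x index pair with slope, se,
#'   t, p and n_years; attribute \code{"exploratory"} is TRUE.
#' @export
annual_env_association <- function(samples, env) {
  check_columns(samples, c("year", "d2H", "d13C", "d15N"), "sample table")
  check_columns(env, c("year", "nao", "ndvi", "rain_mm"), "env table")
  yearly <- stats::aggregate(
    samples[, c("d2H", "d13C", "d15N")],
    by = list(year = samples$year), FUN = mean, na.rm = TRUE)
  m <- merge(yearly, env, by = "year")
  if (nrow(m) < 3) stop("need at least 3 years with both isotope and env data")
  rows <- list()
  for (iso in c("d2H", "d13C", "d15N")) {
    for (ix in c("nao", "ndvi", "rain_mm")) {
      if (stats::var(m[[ix]]) == 0) {
        stop("environmental index '", ix, "' has no variance across years")
      }
      fit <- stats::lm(m[[iso]] ~ m[[ix]])
      cf <- stats::coef(summary(fit))
      rows[[paste(iso, ix)]] <- data.frame(
        isotope = iso, index = ix, slope = cf[2, 1], se = cf[2, 2],
        statistic = cf[2, 3], p = cf[2, 4], n_years = nrow(m),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exploratory") <- TRUE
  out
}
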