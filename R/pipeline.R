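# End-to-end orchestration: simulate (or ingest) -> isoscape transforms ->
# assignment -> phenotype battery -> return battery, with a run manifest.

#' Read a pipeline configuration file
#'
#' YAML with sections mirroring the module names; any missing entry falls
#' back to the package default. The \code{simulate} section accepts every
#' \code{\link{sim_config}} argument; \code{assignment} accepts
#' \code{mass}, \code{sigma_h}, \code{sigma_c} and \code{bbox};
#' \code{inputs} may instead point at user-supplied isoscape (.asc) and
#' table (.csv) files.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  yaml::read_yaml(path)
}

build_sim_config <- function(cfg, seed = NULL) {
  args <- cfg$simulate %||% list()
  if (!is.null(args$year_counts)) {
    args$year_counts <- unlist(args$year_counts)
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or ingestion of user files named in
#' the configuration), deuterium calibration and carbon discrimination,
#' alignment and masking, per-record assignment with per-group count
#' surfaces, the phenotype model battery (repeatability per isotope, the
#' blackness mixed model, the dispersion check, the between-year change
#' model, the exploratory environment associations) and the 12-model return
#' battery with risk curves. All outputs are written under \code{outdir} as
#' ASCII grids and CSV tables, and a JSON run manifest (configuration
#' snapshot, seed, package version, input checksums, per-stage timings and
#' status, output inventory) is written even if a stage fails.
#'
#' @param config configuration list (see \code{\link{read_run_config}}) or
#'   path to a YAML file; \code{NULL} runs the package defaults.
#' @param outdir output directory, created if needed.
#' @param seed root seed overriding the configuration's.
#' @return the manifest, invisibly.
#' @export
run_all <- function(config = NULL, outdir = "winterscape-run", seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- config %||% list()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "winterscape",
    version = as.character(utils::packageVersion("winterscape")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, stages = list(), outputs = character())
  t_all <- proc.time()[["elapsed"]]
  state <- new.env(parent = emptyenv())
  add_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(value = expr, error = NULL),
                    error = function(e) list(value = NULL,
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = if (is.null(res$error)) "ok" else "failed",
      error = res$error,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    if (!is.null(res$error)) {
      stop("stage '", name, "' failed: ", res$error, call. = FALSE)
    }
    res$value
  }
  on.exit({
    manifest$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 3)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  })

  # --- simulate or ingest -------------------------------------------------
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    need <- c("h_isoscape", "c_isoscape", "samples", "env")
    missing <- need[vapply(need, function(k) is.null(inp[[k]]), logical(1))]
    if (length(missing)) {
      stop("simulation disabled but inputs are missing keys: ",
           paste(missing, collapse = ", "))
    }
    sim <- stage("ingest", {
      manifest$checksums <- as.list(tools::md5sum(unlist(inp[need])))
      list(isoscapes = list(
             h = read_isoscape(inp$h_isoscape, isotope = "d2H"),
             c = read_isoscape(inp$c_isoscape, isotope = "d13C")),
           samples = utils::read.csv(inp$samples),
           env = utils::read.csv(inp$env),
           returns = if (!is.null(inp$returns))
             utils::read.csv(inp$returns) else NULL)
    })
    scfg <- NULL
  } else {
    scfg <- build_sim_config(config, seed)
    manifest$seed <- scfg$seed
    sim <- stage("simulate", simulate_dataset(scfg))
    stage("write_simulated", {
      write_isoscape(sim$isoscapes$h,
                     file.path(outdir, "isoscape_d2H_precip.asc"))
      write_isoscape(sim$isoscapes$c,
                     file.path(outdir, "isoscape_d13C_plant.asc"))
      utils::write.csv(
        sim$samples[, c("id", "year", "age", "blackness_pct",
                        "d13C", "d15N", "d2H")],
        file.path(outdir, "samples.csv"), row.names = FALSE)
      utils::write.csv(sim$env, file.path(outdir, "env.csv"),
                       row.names = FALSE)
      utils::write.csv(
        sim$returns[, c("id", "year", "age_first", "returned")],
        file.path(outdir, "returns.csv"), row.names = FALSE)
      add_output(file.path(outdir, c(
        "isoscape_d2H_precip.asc", "isoscape_d13C_plant.asc",
        "samples.csv", "env.csv", "returns.csv")))
    })
  }

  # --- isoscape transforms + assignment ----------------------------------
  acfg <- config$assignment %||% list()
  assign_res <- stage("assignment", {
    params <- calibration_params()
    hs <- if (sim$isoscapes$h$calibrated) sim$isoscapes$h else
      calibrate_h(sim$isoscapes$h, params)
    cs <- if (sim$isoscapes$c$calibrated) sim$isoscapes$c else
      discriminate_c(sim$isoscapes$c, params)
    al <- align_and_mask(list(hs, cs), bbox = acfg$bbox)
    assign_all(sim$samples, al[[1]], al[[2]],
               mass = acfg$mass %||% (2 / 3),
               sigma_h = acfg$sigma_h, sigma_c = acfg$sigma_c)
  })
  stage("write_assignment", {
    utils::write.csv(assign_res$summary,
                     file.path(outdir, "assignment_summary.csv"),
                     row.names = FALSE)
    add_output(file.path(outdir, "assignment_summary.csv"))
    for (g in names(assign_res$count_surfaces)) {
      csf <- assign_res$count_surfaces[[g]]
      iso <- isoscape(matrix(as.numeric(csf$counts), nrow(csf$counts)),
                      csf$extent, sigma = 1, isotope = "count")
      f <- file.path(outdir, sprintf("counts_%s.asc", g))
      write_isoscape(iso, f)
      add_output(f)
    }
  })

  # --- phenotype battery --------------------------------------------------
  pcfg <- config$phenotype %||% list()
  pheno <- stage("phenotype_models", {
    smp <- sim$samples
    rpt <- lapply(c(d13C = "d13C", d15N = "d15N", d2H = "d2H",
                    blackness = "blackness_pct"),
                  function(v) repeatability(smp[[v]], smp$id,
                                            n_boot = pcfg$n_boot %||% 200,
                                            seed = scfg$seed %||% 1L))
    list(repeatability = rpt,
         blackness_lmm = fit_blackness_lmm(smp),
         dispersion = residual_dispersion_vs_blackness(smp),
         change = tryCatch(between_year_change_model(smp),
                           error = function(e) conditionMessage(e)),
         env_assoc = annual_env_association(smp, sim$env))
  })
  stage("write_phenotype", {
    rpt_df <- do.call(rbind, lapply(names(pheno$repeatability), function(v) {
      r <- pheno$repeatability[[v]]
      data.frame(variable = v, R = r$R, ci_lo = r$ci[1], ci_hi = r$ci[2],
                 p = r$p, n_id = r$n_id, n_obs = r$n_obs)
    }))
    utils::write.csv(rpt_df, file.path(outdir, "repeatability.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(pheno$blackness_lmm),
                     file.path(outdir, "blackness_lmm.csv"),
                     row.names = FALSE)
    utils::write.csv(pheno$env_assoc,
                     file.path(outdir, "env_associations.csv"),
                     row.names = FALSE)
    add_output(file.path(outdir, c("repeatability.csv", "blackness_lmm.csv",
                                   "env_associations.csv")))
  })

  # --- return battery -----------------------------------------------------
  if (!is.null(sim$returns)) {
    rcfg <- config$return_models %||% list()
    battery <- stage("return_models",
                     run_battery(sim$returns,
                                 method = rcfg$method %||% "coxph"))
    stage("write_returns", {
      utils::write.csv(battery, file.path(outdir, "return_battery.csv"),
                       row.names = FALSE)
      add_output(file.path(outdir, "return_battery.csv"))
      fits <- attr(battery, "fits")
      hn <- Filter(function(f) f$converged && f$predictor == "d2H" &&
                     f$env == "nao", fits)
      if (length(hn)) {
        rng <- range(sim$returns$d2H, na.rm = TRUE)
        risk <- predict_risk(hn[[1]],
                             seq(rng[1], rng[2], length.out = 50),
                             sim$returns$nao)
        utils::write.csv(risk, file.path(outdir, "risk_d2H_nao.csv"),
                         row.names = FALSE)
        add_output(file.path(outdir, "risk_d2H_nao.csv"))
      }
    })
  }
  invisible(manifest)
}
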