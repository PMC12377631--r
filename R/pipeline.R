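#' Run a multi-stage analysis pipeline from a configuration
#'
#' Executes the requested stages in a fixed order - `classify`,
#' `potential`, `plan_dose`, `simulate`, `periodic_scan`, `lyapunov`,
#' `synth`, `fit` - writing one JSON result per stage plus a run manifest
#' (package/R versions, seed, input digests, per-stage status and output
#' files). An empty stage list produces the manifest only. Runs are
#' deterministic for a fixed configuration: every random stage draws from
#' the configured seed.
#'
#' Configuration blocks (YAML or JSON file, or an equivalent nested
#' list):
#' \describe{
#'   \item{stages}{character vector of stage names (see above).}
#'   \item{kinetics}{either `fixture: <name>` referring to
#'     [lv_fixtures()], or the named kinetic parameters for
#'     [lv_params()].}
#'   \item{therapy}{arguments for [therapy_spec()].}
#'   \item{simulation}{`state0`, `t_end`, `n_out`, `rtol`, `atol`.}
#'   \item{periodic_scan}{`omegas` vector plus optional strobe settings.}
#'   \item{lyapunov}{`A`, `omega` and [lyapunov_settings()] fields.}
#'   \item{synth}{[synthetic_spec()] fields (`sigma`, `times`, ...).}
#'   \item{fit}{`input` path to a `t,V` file (defaults to the synth stage
#'     output), `n_starts`, plus bound overrides.}
#'   \item{seed}{integer seed for all random stages.}
#' }
#'
#' @param config path to a YAML/JSON configuration file, or a list.
#' @param out_dir output directory (created if missing); defaults to the
#'   `out_dir` config entry or `tempfile("lvtumor_run")`.
#' @return The manifest, invisibly, of class `lv_manifest`; its
#'   `status` is `"ok"` only if every requested stage succeeded.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_digest <- NA_character_
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg_digest <- unname(tools::md5sum(config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("lvtumor_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  params <- NULL
  therapy <- NULL
  if (!is.null(config$kinetics)) {
    kin <- config$kinetics
    params <- if (!is.null(kin$fixture)) {
      fx <- lv_fixtures()[[kin$fixture]]
      if (is.null(fx)) stop("unknown fixture: ", kin$fixture)
      fx$kinetics
    } else do.call(lv_params, kin)
  }
  if (!is.null(config$therapy))
    therapy <- do.call(therapy_spec, config$therapy)

  stages <- config$stages
  order <- c("classify", "potential", "plan_dose", "simulate",
             "periodic_scan", "lyapunov", "synth", "fit")
  if (is.null(stages)) stages <- character(0)
  unknown <- setdiff(stages, order)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- order[order %in% stages]

  manifest <- list(package = "lvtumor",
                   version = as.character(utils::packageVersion("lvtumor")),
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed, config_digest = cfg_digest,
                   stages = list(), outputs = character(0),
                   status = "ok")
  synth_path <- NULL

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      manifest$status <<- "failed"
    } else {
      path <- file.path(out_dir, paste0(name, ".json"))
      write_results(res, path)
      manifest$stages[[name]] <<- list(status = "ok", output = path)
      manifest$outputs <<- c(manifest$outputs, path)
    }
  }

  for (st in stages) {
    switch(st,
      classify = run_stage("classify", function() {
        dp <- to_dimensionless(params)
        list(dimensionless = unclass(dp),
             regime = classify_regime(dp),
             equilibria = equilibria(dp),
             dulac = dulac_certificate(dp))
      }),
      potential = run_stage("potential", function() {
        prof <- potential_profile(to_dimensionless(params))
        list(case = prof$case_label, coefficients = prof$coefficients,
             extrema = prof$extrema)
      }),
      plan_dose = run_stage("plan_dose", function() {
        if (is.null(therapy)) stop("plan_dose stage needs a therapy block")
        if (therapy$mode == "proportional_constant")
          plan_outcome(params, therapy$beta_x, therapy$beta_y, therapy$D)
        else
          plan_outcome_additive(params, beta_y = therapy$beta_y,
                                D = therapy$D)
      }),
      simulate = run_stage("simulate", function() {
        sim <- config$simulation
        state0 <- if (is.null(sim$state0))
          c(0.5 * params$Kx, 0.5 * params$Ky) else unlist(sim$state0)
        tr <- lv_simulate(state0, params, therapy,
                          t_end = if (is.null(sim$t_end)) 100 else sim$t_end,
                          n_out = if (is.null(sim$n_out)) 200L else sim$n_out,
                          rtol = if (is.null(sim$rtol)) 1e-8 else sim$rtol,
                          atol = if (is.null(sim$atol)) 1e-10 else sim$atol)
        txt <- file.path(out_dir, "trajectory.csv")
        write_trajectory(tr, txt)
        manifest$outputs <<- c(manifest$outputs, txt)
        list(samples = nrow(tr), file = txt,
             final_state = as.numeric(tr[nrow(tr), 2:3]))
      }),
      periodic_scan = run_stage("periodic_scan", function() {
        ps <- config$periodic_scan
        if (is.null(ps$omegas)) stop("periodic_scan needs an omegas vector")
        tab <- amplitude_vs_frequency(params, therapy, unlist(ps$omegas))
        txt <- file.path(out_dir, "periodic_scan.csv")
        utils::write.table(tab, txt, sep = ",", row.names = FALSE,
                           quote = FALSE)
        manifest$outputs <<- c(manifest$outputs, txt)
        tab
      }),
      lyapunov = run_stage("lyapunov", function() {
        ly <- config$lyapunov
        dp <- if (!is.null(ly$c)) dimensionless_params(ly$c, ly$d, ly$f)
              else to_dimensionless(params)
        st <- lyapunov_settings(
          tau_renorm = if (is.null(ly$tau_renorm)) 0.1 else ly$tau_renorm,
          h = if (is.null(ly$h)) 0.02 else ly$h,
          n_steps = if (is.null(ly$n_steps)) 3000L else ly$n_steps)
        res <- lyapunov_spectrum(dp, A = if (is.null(ly$A)) 0 else ly$A,
                                 omega = if (is.null(ly$omega)) 0
                                         else ly$omega,
                                 settings = st)
        txt <- file.path(out_dir, "sigma_sequence.csv")
        utils::write.table(sigma_sequence(res), txt, sep = ",",
                           row.names = FALSE, quote = FALSE)
        manifest$outputs <<- c(manifest$outputs, txt)
        list(spectrum = res$spectrum, max_exponent = res$max_exponent,
             converged = res$converged, params = res$params,
             settings = res$settings, trace_file = txt)
      }),
      synth = run_stage("synth", function() {
        sy <- if (is.null(config$synth)) list() else config$synth
        spec <- synthetic_spec(
          params = params,
          state0 = if (is.null(sy$state0)) NULL else unlist(sy$state0),
          times = if (is.null(sy$times)) seq(0, 30, length.out = 12)
                  else unlist(sy$times),
          sigma = if (is.null(sy$sigma)) 0.05 else sy$sigma,
          seed = seed)
        series <- generate_volume_series(spec)
        synth_path <<- file.path(out_dir, "volumes.csv")
        write_volume_series(series, synth_path)
        manifest$outputs <<- c(manifest$outputs, synth_path)
        list(file = synth_path, n = nrow(series), sigma = spec$sigma)
      }),
      fit = run_stage("fit", function() {
        fc <- if (is.null(config$fit)) list() else config$fit
        input <- if (!is.null(fc$input)) fc$input else synth_path
        if (is.null(input)) stop("fit stage needs an input file or a synth stage")
        series <- read_volume_series(input)
        fit <- fit_lv(series,
                      n_starts = if (is.null(fc$n_starts)) 20L
                                 else fc$n_starts,
                      seed = seed)
        rep <- goodness_report(fit)
        list(theta = as.list(fit$theta), rss = fit$rss,
             converged = fit$converged, identifiable = fit$identifiable,
             residuals = rep$residuals)
      }))
  }

  write_results(manifest, file.path(out_dir, "manifest.json"))
  class(manifest) <- "lv_manifest"
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}

#' @export
print.lv_manifest <- function(x, ...) {
  cat(sprintf("lvtumor pipeline run (%s), status: %s\n", x$timestamp,
              x$status))
  for (nm in names(x$stages))
    cat(sprintf("  %-14s %s\n", nm, x$stages[[nm]]$status))
  cat("  outputs in ", attr(x, "out_dir"), "\n")
  invisible(x)
}
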