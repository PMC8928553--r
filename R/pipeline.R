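#' Read and write pipeline configurations
#'
#' A pipeline configuration is a YAML document describing which stages
#' to run (design, simulate, fit, desirability, modr, validate) and
#' with what parameters; [run_pipeline()] executes it.  Two packaged
#' configurations serve as worked examples:
#' `"modr-verification"` (evaluate the packaged CMA models over the
#' established MODR box and confirm every node passes) and
#' `"synthetic-recovery"` (simulate DoE responses from the packaged
#' models, refit the declared term sets, and compare working-point
#' predictions).
#'
#' @param path file path of a YAML configuration, or the name of a
#'   packaged configuration.
#' @return `read_pipeline_config()`: a list of class
#'   `pipeline_config`.
#' @examples
#' cfg <- read_pipeline_config("modr-verification")
#' cfg$name
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    packaged <- system.file("extdata", "config",
                            paste0(gsub("-", "_", path), ".yaml"),
                            package = "aqbd")
    if (nzchar(packaged)) path <- packaged
    else stop_aqbd("config file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name)) stop_aqbd("config must have a name")
  cfg$config_path <- normalizePath(path)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` list.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$config_path <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_factor_space <- function(cfg) {
  fsc <- cfg$factor_space %||% list(source = "packaged",
                                    stage = "optimization")
  if (identical(fsc$source, "packaged"))
    cabotegravir_factor_space(fsc$stage %||% "optimization")
  else
    fixture_space(fsc$factors)
}

config_models <- function(cfg) {
  mc <- cfg$models %||% list(source = "packaged", stage = "optimization")
  if (identical(mc$source, "packaged"))
    cabotegravir_models(mc$stage %||% "optimization")
  else {
    mods <- lapply(mc$list, function(r)
      response_model(r$response, unlist(r$coefficients),
                     transform = r$transform %||% "identity"))
    setNames(mods, vapply(mods, `[[`, character(1), "response"))
  }
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run an AQbD pipeline from a configuration
#'
#' Executes the stages declared in a [read_pipeline_config()]
#' configuration in their natural order — optimal design, response
#' simulation, model fitting, desirability search, MODR mapping,
#' validation screening — and writes every stage's result to
#' `out_dir` (design and response CSVs, fit report JSON, MODR JSON +
#' long-format grid CSV, validation report JSON) together with a
#' provenance log carrying the configuration hash, package version and
#' seeds.  Given identical configuration and seed, all numeric outputs
#' are reproduced exactly.
#'
#' @param config a `pipeline_config`, or a path / packaged name
#'   accepted by [read_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the configuration seed.
#' @return Invisibly, a list with the per-stage results and the
#'   provenance record.
#' @examples
#' \donttest{
#' res <- run_pipeline("modr-verification", tempfile("aqbd"))
#' res$modr$box
#' }
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (!inherits(config, "pipeline_config"))
    config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- seed %||% config$seed %||% 1L
  space <- config_factor_space(config)
  models <- config_models(config)
  results <- list()
  stages <- character(0)
  timings <- numeric(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop_aqbd("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    stages <<- c(stages, name)
    timings <<- c(timings, proc.time()[["elapsed"]] - t0)
    r
  }

  design <- NULL
  if (!is.null(config$design)) {
    dcfg <- config$design
    design <- stage("design", {
      if (identical(dcfg$method %||% "exchange", "factorial")) {
        g <- candidate_grid(space, unlist(dcfg$levels %||% c(-1, 0, 1)))
        g$replicate_group <- NA_integer_
        ncr <- dcfg$center_replicates %||% 3
        if (ncr > 0) {
          center <- as.data.frame(as.list(setNames(rep(0, length(factor_names(space))),
                                                   factor_names(space))))
          center <- center[rep(1, ncr), , drop = FALSE]
          center$replicate_group <- 1L
          g <- rbind(g, center)
        }
        g <- cbind(run_id = seq_len(nrow(g)), g)
        rownames(g) <- NULL
        g
      } else {
        exchange_design(terms = unlist(dcfg$terms),
                        candidates = candidate_grid(space,
                                                    unlist(dcfg$levels %||% c(-1, 0, 1))),
                        n_runs = dcfg$n_runs,
                        criterion = dcfg$criterion %||% "A",
                        n_starts = dcfg$n_starts %||% 10,
                        seed = seed,
                        center_replicates = dcfg$center_replicates %||% 3)$design
      }
    })
    nat <- design_table(design, space)
    write.csv(nat, file.path(out_dir, "design.csv"), row.names = FALSE)
    results$design <- design
  }

  responses <- NULL
  if (!is.null(config$simulate)) {
    if (is.null(design))
      stop_aqbd("pipeline stage 'simulate' needs a design stage")
    responses <- stage("simulate", {
      simulate_doe_responses(models, design,
                             noise_sd = config$simulate$noise_sd %||% 0,
                             seed = seed + 1L)
    })
    write.csv(responses, file.path(out_dir, "responses.csv"),
              row.names = FALSE)
    results$responses <- responses
  }

  if (!is.null(config$fit)) {
    if (is.null(responses))
      stop_aqbd("pipeline stage 'fit' needs simulated or loaded responses")
    fits <- stage("fit", {
      lapply(names(config$fit$responses), function(rn) {
        fcfg <- config$fit$responses[[rn]]
        fit_rsm(design, responses[[rn]],
                terms = unlist(fcfg$terms),
                transform = fcfg$transform %||% "identity",
                response = rn)
      })
    })
    names(fits) <- names(config$fit$responses)
    report <- lapply(fits, function(f) list(
      response = f$response,
      coefficients = as.list(f$coefficients),
      std_errors = as.list(f$se),
      anova = f$anova,
      residuals = f$residuals))
    write_json_report(report, file.path(out_dir, "fit_report.json"))
    results$fits <- fits
  }

  if (!is.null(config$desirability)) {
    dcfg <- config$desirability
    des <- stage("desirability", {
      rules <- lapply(dcfg$rules, function(r)
        desirability_rule(r$criterion, r$anchor_zero, r$anchor_one,
                          r$weight %||% 1))
      grid <- candidate_grid(space, unlist(dcfg$grid_levels %||% c(-1, -0.5, 0, 0.5, 1)))
      best_answer_search(models, rules, grid)
    })
    write_json_report(list(point = as.list(des$point), score = des$score),
                      file.path(out_dir, "desirability.json"))
    results$desirability <- des
  }

  if (!is.null(config$modr)) {
    mcfg <- config$modr
    modr <- stage("modr", {
      pert <- if (!is.null(mcfg$perturbation)) {
        p <- mcfg$perturbation
        perturbation_spec(sd = unlist(p$sd),
                          n_draws = p$n_draws %||% 10000,
                          seed = seed + 2L)
      }
      map_modr(models, space,
               box = if (!is.null(mcfg$box)) lapply(mcfg$box, as.numeric),
               levels = mcfg$levels %||% 9,
               threshold = mcfg$threshold %||% 2.0,
               pert = pert,
               cpk_min = mcfg$cpk_min %||% 1.33)
    })
    write.csv(as.data.frame(modr), file.path(out_dir, "modr_grid.csv"),
              row.names = FALSE)
    wp <- if (!is.null(mcfg$working_point)) unlist(mcfg$working_point)
    else cabotegravir_working_point()
    wrep <- working_point_report(models, wp, space)
    write_json_report(list(
      n_nodes = nrow(modr$grid), n_pass = sum(modr$pass),
      all_pass = all(modr$pass), box = modr$box,
      working_point = as.list(wp),
      working_point_predictions = setNames(as.list(wrep$prediction),
                                           wrep$response)),
      file.path(out_dir, "modr.json"))
    results$modr <- modr
    results$working_point <- wrep
  }

  if (isTRUE(config$validate)) {
    val <- stage("validate", check_limits(validation_tables()))
    write_json_report(val, file.path(out_dir, "validation.json"))
    results$validation <- val
  }

  cfg_tmp <- file.path(out_dir, "config_used.yaml")
  write_pipeline_config(config, cfg_tmp)
  provenance <- list(
    config_name = config$name,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    package_version = as.character(utils::packageVersion("aqbd")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    stages = as.list(setNames(round(timings, 3), stages)))
  write_json_report(provenance, file.path(out_dir, "provenance.json"))
  results$provenance <- provenance
  invisible(results)
}
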