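RUN_CONFIG_KEYS <- list(
  seed = "integer",
  output_dir = "character",
  speciation = c("total_citrate", "pH", "pKa"),
  rate_parameters = c("k_ta", "l", "k_cit", "k_pass", "au_order_ta"),
  kinetics = c("c_precursor", "c_ta", "c_nacit", "pH", "t_max", "n_points"),
  fit_order = c("ta_min", "ta_max", "n_points"),
  size = c("d_seed", "gold_ratio"),
  recipe = c("d_seed", "targets", "labels"),
  colorimetry = c("roi", "window", "plateau_k", "method")
)

#' Default pipeline configuration
#'
#' The full configuration schema with the package defaults: seed-recipe
#' concentrations, calibrated rate parameters, the published growth-round
#' targets and colorimetry settings. Individual blocks can be overridden in
#' a YAML/JSON file read with [read_run_config()].
#'
#' @param output_dir Directory pipeline artifacts are written to.
#' @param seed Global seed fanned out to the pipeline's random streams.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(output_dir = tempfile("tacit-run-"),
                               seed = 1L) {
  validate_run_config(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    speciation = list(total_citrate = 2.2e-3, pH = 7.7,
                      pKa = unname(citrate_pka())),
    rate_parameters = list(k_ta = 600, l = 1.1, k_cit = 2000, k_pass = 100,
                           au_order_ta = 1),
    kinetics = list(c_precursor = 1.25e-4, c_ta = 1e-4, c_nacit = 2.2e-3,
                    pH = 7.7, t_max = 300, n_points = 151),
    fit_order = list(ta_min = 2e-5, ta_max = 2e-4, n_points = 8),
    size = list(d_seed = 3, gold_ratio = 1.4),
    recipe = list(d_seed = 3, targets = NULL, labels = NULL),
    colorimetry = list(roi = NULL, window = 0.1, plateau_k = 5,
                       method = "pixel_mean")
  ))
}

#' Validate a pipeline configuration
#'
#' Checks the configuration against the schema before any stage runs:
#' unknown top-level keys and unknown keys inside a block are rejected, and
#' missing blocks are filled from [default_run_config()].
#'
#' @param config A named list (e.g. parsed from YAML/JSON).
#' @return The completed configuration, classed `run_config`.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a named list", call. = FALSE)
  unknown <- setdiff(names(config), names(RUN_CONFIG_KEYS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (block in intersect(names(config), names(RUN_CONFIG_KEYS))) {
    allowed <- RUN_CONFIG_KEYS[[block]]
    if (is.list(config[[block]]) && !allowed[1] %in% c("integer", "character")) {
      bad <- setdiff(names(config[[block]]), allowed)
      if (length(bad)) {
        stop(sprintf("unknown key(s) in config block '%s': %s", block,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
  }
  structure(config, class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config` with unset blocks filled from
#'   [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- validate_run_config(cfg)
  base <- unclass(default_run_config())
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  validate_run_config(base)
}

provenance_header <- function(config, stage) {
  c(sprintf("# tacit %s | stage %s",
            as.character(utils::packageVersion("tacit")), stage),
    sprintf("# config_hash %s | seed %d",
            rlang::hash(unclass(config)[setdiff(names(config),
                                                "output_dir")]),
            as.integer(config$seed %||% NA_integer_)))
}

write_csv_artifact <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, stage), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read a kinetic trace as CSV
#'
#' Fixed header `t_s, c_precursor_M, c_passivated_M, c_reduced_M, c_ta_M,
#' c_cit_reactive_M`; provenance lines are `#` comments.
#'
#' @param trace A `kinetic_trace`.
#' @param path Output/input CSV path.
#' @param c_oh Hydroxide level restored onto a read trace (mol/L).
#' @return The path (write) or a `kinetic_trace` (read).
#' @export
write_kinetic_trace <- function(trace, path) {
  cols <- c("t_s", "c_precursor_M", "c_passivated_M", "c_reduced_M",
            "c_ta_M", "c_cit_reactive_M")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tacit %s | kinetic_trace | provenance %s | c_oh %.12g",
                     as.character(utils::packageVersion("tacit")),
                     attr(trace, "provenance") %||% "simulated",
                     attr(trace, "c_oh") %||% NA_real_), con)
  utils::write.csv(as.data.frame(trace)[, cols], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinetic_trace
#' @export
read_kinetic_trace <- function(path, c_oh = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(c_oh) && grepl("c_oh ", first)) {
    c_oh <- suppressWarnings(as.numeric(sub(".*c_oh ", "", first)))
  }
  df <- utils::read.csv(path, comment.char = "#")
  new_kinetic_trace(tibble::as_tibble(df),
                    c_oh = if (is.null(c_oh) || is.na(c_oh))
                      10^(7.7 - 14) else c_oh,
                    provenance = if (grepl("synthetic-noisy", first))
                      "synthetic-noisy" else "simulated")
}

#' Write / read a frame series as PNG files plus a timestamp manifest
#'
#' Frames are written as `frame_0001.png`, ... with a `manifest.csv`
#' (`file`, `t_s`) in the same directory.
#'
#' @param series A [frame_series()].
#' @param dir Directory to write to / read from.
#' @return The directory (write) or a [frame_series()] (read).
#' @export
write_frame_series <- function(series, dir) {
  stopifnot(inherits(series, "frame_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%04d.png", seq_along(series$frames))
  for (i in seq_along(series$frames)) {
    png::writePNG(series$frames[[i]] / 255, file.path(dir, files[i]))
  }
  utils::write.csv(data.frame(file = files, t_s = series$timestamps),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_frame_series
#' @export
read_frame_series <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  frames <- lapply(manifest$file, function(f) {
    img <- png::readPNG(file.path(dir, f))
    round(img[, , 1:3, drop = FALSE] * 255)
  })
  frame_series(manifest$t_s, frames)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order against a validated
#' configuration, writing one CSV artifact per stage (each with a
#' provenance header carrying the package version, config hash and seed)
#' into `config$output_dir`. An empty stage selection is a no-op.
#'
#' Stages: `"speciate"` (citrate speciation profile), `"simulate"` (kinetic
#' trace at the configured conditions), `"fit-order"` (initial rates over a
#' TA grid and the log-log reaction order), `"size-predict"` (selectivity
#' and final diameter), `"simulate-recipe"` (round-by-round seeded-growth
#' report), `"dilution"` (equal-surface-area dilution factors for the
#' published series).
#'
#' @param config A `run_config` (default [default_run_config()]).
#' @param stages Character subset of the stage names above, in any order.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = character()) {
  config <- validate_run_config(unclass(config))
  known <- c("speciate", "simulate", "fit-order", "size-predict",
             "simulate-recipe", "dilution")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(stages) == 0L) return(invisible(list()))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- known[known %in% stages]  # dependency order
  params <- do.call(rate_parameters, config$rate_parameters)
  artifacts <- list()

  kin_initial <- function() {
    kc <- config$kinetics
    spec <- speciate_citrate(kc$c_nacit, kc$pH, config$speciation$pKa)
    reaction_state(c_precursor = kc$c_precursor, c_ta = kc$c_ta,
                   c_cit_reactive = spec$c_CtH2_minus,
                   c_oh = 10^(kc$pH - 14))
  }

  for (stage in stages) {
    t0 <- Sys.time()
    out <- switch(
      stage,
      "speciate" = {
        sp <- speciation_profile(config$speciation$total_citrate,
                                 seq(0, 14, by = 0.1),
                                 config$speciation$pKa)
        write_csv_artifact(sp, file.path(config$output_dir, "speciation.csv"),
                           config, stage)
      },
      "simulate" = {
        kc <- config$kinetics
        tr <- simulate_reduction(kin_initial(), params,
                                 seq(0, kc$t_max, length.out = kc$n_points))
        write_kinetic_trace(tr, file.path(config$output_dir, "trace.csv"))
      },
      "fit-order" = {
        fo <- config$fit_order
        ta_grid <- exp(seq(log(fo$ta_min), log(fo$ta_max),
                           length.out = fo$n_points))
        base <- kin_initial()
        rates <- vapply(ta_grid, function(cta) {
          st <- base
          st$c_ta <- cta
          reduction_rate_ta(st, params)
        }, numeric(1))
        ord <- fit_reaction_order(rates, ta_grid)
        write_csv_artifact(
          tibble::tibble(c_ta_M = ta_grid, rate_M_s = rates,
                         order = ord$order,
                         log_intercept = ord$log_intercept),
          file.path(config$output_dir, "reaction_order.csv"), config, stage)
      },
      "size-predict" = {
        base <- kin_initial()
        sigma <- selectivity(
          selectivity_inputs(base$c_cit_reactive, base$c_ta, base$c_oh),
          params)
        pred <- predict_final_diameter(config$size$d_seed, sigma,
                                       config$size$gold_ratio)
        write_csv_artifact(pred,
                           file.path(config$output_dir,
                                     "size_prediction.csv"), config, stage)
      },
      "simulate-recipe" = {
        rc <- config$recipe
        recipe <- if (is.null(rc$targets)) default_recipe() else {
          default_recipe(rounds = lapply(seq_along(rc$targets), function(i) {
            synthesis_round(i, rc$targets[[i]],
                            label = rc$labels[[i]] %||% paste0("round_", i))
          }))
        }
        report <- simulate_recipe(recipe, d_seed = rc$d_seed)
        write_csv_artifact(report,
                           file.path(config$output_dir, "recipe_report.csv"),
                           config, stage)
      },
      "dilution" = {
        tab <- published_round_targets()
        dfs <- dilution_factors(tibble::tibble(
          label = tab$label, c_au_M = tab$c_au_M,
          d_core_nm = tab$d_nominal_nm))
        write_csv_artifact(dfs,
                           file.path(config$output_dir,
                                     "dilution_factors.csv"), config, stage)
      })
    artifacts[[stage]] <- out
    message(sprintf("[tacit] stage %-15s %6.2f s -> %s", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    out))
  }
  invisible(artifacts)
}
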