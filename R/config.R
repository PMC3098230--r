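#' Load and validate a run configuration
#'
#' A configuration file (YAML, or JSON by `.json` extension) selects a model
#' (`generic`, `model1` or `model2` block — exactly one), an `analysis`
#' (`steady-states`, `bifurcate`, `manifold`, `simulate` or `reduce`), and
#' optional analysis blocks (`bifurcation`, `manifold`, `simulation`) plus a
#' `seed`. Unknown keys anywhere are rejected; all defaults are filled in so
#' the returned object is fully explicit.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return An object of class `run_config`: list with `analysis`,
#'   `model_type`, `params` (a constructed parameter object), `options`
#'   (analysis settings with defaults filled) and `seed`.
#' @seealso [run_config()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

validate_config <- function(raw) {
  known_top <- c("analysis", "generic", "model1", "model2",
                 "bifurcation", "manifold", "simulation", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  model_blocks <- intersect(c("generic", "model1", "model2"), names(raw))
  if (length(model_blocks) != 1L) {
    stop("exactly one of `generic`, `model1`, `model2` must be given (found ",
         length(model_blocks), ").", call. = FALSE)
  }
  model_type <- model_blocks
  analyses <- c("steady-states", "bifurcate", "manifold", "simulate", "reduce")
  analysis <- raw$analysis %||% "steady-states"
  if (!analysis %in% analyses) {
    stop("`analysis` must be one of: ", paste(analyses, collapse = ", "),
         call. = FALSE)
  }
  params <- build_params(model_type, raw[[model_type]])
  options <- fill_option_defaults(raw)
  seed <- raw$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` must be a single integer.", call. = FALSE)
  }
  structure(
    list(analysis = analysis, model_type = model_type, params = params,
         options = options, seed = as.integer(seed)),
    class = "run_config"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

build_params <- function(model_type, block) {
  if (is.null(block) || !is.list(block)) {
    stop(sprintf("`%s` must be a mapping of parameter names to values.",
                 model_type), call. = FALSE)
  }
  ctor <- switch(model_type,
                 generic = generic_params,
                 model1 = model1_params,
                 model2 = model2_params)
  allowed <- names(formals(ctor))
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown `%s` parameter(s): %s", model_type,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  tryCatch(do.call(ctor, lapply(block, as.numeric)),
           error = function(e) {
             stop(sprintf("invalid `%s` block: %s", model_type,
                          conditionMessage(e)), call. = FALSE)
           })
}

fill_option_defaults <- function(raw) {
  defaults <- list(
    bifurcation = list(q_min = 0.2, q_max = 5, n_q = 101),
    manifold = list(n_points = 200),
    simulation = list(sigma = 0.05, dt = 0.01, n_steps = 1e6,
                      burn_in_fraction = 0.1, init = c(1, 1), n_bins = 100,
                      rel_threshold = 0.1, min_separation = 0.5,
                      ensemble = FALSE)
  )
  for (blk in names(defaults)) {
    given <- raw[[blk]] %||% list()
    unknown <- setdiff(names(given), names(defaults[[blk]]))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown `%s` option(s): %s", blk,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    defaults[[blk]][names(given)] <- given
  }
  defaults
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  analysis: %s | model: %s | seed: %d\n",
              x$analysis, x$model_type, x$seed))
  print(x$params)
  invisible(x)
}

#' Write a run configuration back to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg` for any valid configuration.
#'
#' @param cfg A `run_config`.
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  pl <- unclass(cfg$params)
  if (cfg$model_type == "generic") {
    pl <- list(a = pl$a, f = pl$f, b = c(pl$bx, pl$by),
               c = c(pl$cx, pl$cy), d = c(pl$dx, pl$dy))
  }
  out <- c(list(analysis = cfg$analysis, seed = cfg$seed),
           stats::setNames(list(pl), cfg$model_type),
           cfg$options)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the analysis selected by a configuration
#'
#' Dispatches to the package function matching `cfg$analysis` and, when
#' `out_dir` is given, writes its outputs: CSV tables for steady states,
#' bifurcation diagrams, manifold samples and densities, plus a JSON summary
#' for stochastic runs. Every output file starts with comment lines echoing
#' the package version, the full parameter set and the seed, so identical
#' configurations give byte-identical deterministic outputs.
#'
#' @param cfg A `run_config` from [load_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return The analysis result, invisibly: a tibble, a
#'   `bifurcation_diagram`, a `model2_reduction`/`generic_params`, or for
#'   `simulate` a list with the trajectory summary.
#' @export
run_config <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  result <- switch(
    cfg$analysis,
    "reduce" = run_reduce(cfg, out_dir),
    "steady-states" = run_steady_states(cfg, out_dir),
    "bifurcate" = run_bifurcate(cfg, out_dir),
    "manifold" = run_manifold(cfg, out_dir),
    "simulate" = run_simulate(cfg, out_dir)
  )
  invisible(result)
}

# generic parameters for analyses on the reduced system, whichever block the
# config carried
config_generic_params <- function(cfg) {
  if (cfg$model_type == "generic") return(cfg$params)
  if (cfg$model_type == "model1") return(reduce_model1(cfg$params))
  red <- reduce_model2(cfg$params)
  if (!red$factorizes) {
    stop("model2 configuration does not factorize (K_xxy != K_yx); ",
         "no generic-parameter mapping exists for this analysis.",
         call. = FALSE)
  }
  red$generic
}

run_reduce <- function(cfg, out_dir) {
  if (cfg$model_type == "generic") {
    stop("`reduce` needs a model1 or model2 block.", call. = FALSE)
  }
  if (cfg$model_type == "model1") {
    g <- reduce_model1(cfg$params)
    payload <- list(model = "model1", factorizes = TRUE,
                    generic = unclass(g))
  } else {
    red <- reduce_model2(cfg$params)
    payload <- list(model = "model2", factorizes = red$factorizes,
                    coefficients = red$coefficients,
                    generic = if (red$factorizes) unclass(red$generic))
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(payload, file.path(out_dir, "reduced.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  payload
}

run_steady_states <- function(cfg, out_dir) {
  st <- steady_states(config_generic_params(cfg))
  if (!is.null(out_dir)) {
    write_output_csv(st, file.path(out_dir, "steady_states.csv"), cfg)
  }
  st
}

run_bifurcate <- function(cfg, out_dir) {
  opt <- cfg$options$bifurcation
  bd <- bifurcation_sweep(config_generic_params(cfg),
                          q_min = opt$q_min, q_max = opt$q_max, n_q = opt$n_q)
  if (!is.null(out_dir)) {
    write_output_csv(tidy(bd), file.path(out_dir, "diagram.csv"), cfg)
    jsonlite::write_json(list(critical_q = bd$critical_q),
                         file.path(out_dir, "bifurcation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bd
}

run_manifold <- function(cfg, out_dir) {
  p <- config_generic_params(cfg)
  if (!detect_degeneracy(p, tol = 1e-12)) {
    stop("`manifold` requires degenerate parameters (b = c and a = f); ",
         "got b = ", p$bx, ", c = ", p$cx, ".", call. = FALSE)
  }
  mp <- manifold_points(p, n = cfg$options$manifold$n_points)
  if (!is.null(out_dir)) {
    write_output_csv(mp[, c("x", "y", "lambda", "mu")],
                     file.path(out_dir, "manifold.csv"), cfg)
  }
  mp
}

run_simulate <- function(cfg, out_dir) {
  p <- config_generic_params(cfg)
  opt <- cfg$options$simulation
  traj <- if (isTRUE(opt$ensemble)) {
    simulate_ensemble(p, sigma = opt$sigma, dt = opt$dt,
                      n_steps = opt$n_steps, seed = cfg$seed,
                      burn_in_fraction = opt$burn_in_fraction)
  } else {
    simulate_circuit(p, sigma = opt$sigma, dt = opt$dt,
                     n_steps = opt$n_steps, init = opt$init,
                     seed = cfg$seed,
                     burn_in_fraction = opt$burn_in_fraction)
  }
  dens <- stationary_density(traj, n_bins = opt$n_bins)
  modes <- count_modes(dens, rel_threshold = opt$rel_threshold,
                       min_separation = opt$min_separation)
  residence <- if (detect_degeneracy(p)) manifold_residence(traj, p) else NULL
  summary <- list(seed = cfg$seed, n_modes = nrow(modes), modes = modes,
                  manifold_residence = residence, config = opt)
  if (!is.null(out_dir)) {
    write_output_csv(tidy(dens), file.path(out_dir, "density.csv"), cfg)
    jsonlite::write_json(summary, file.path(out_dir, "simulation_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(trajectory = traj, density = dens, modes = modes,
       residence = residence)
}

# CSV with a reproducibility header: package version, parameter echo, seed
write_output_csv <- function(tbl, path, cfg) {
  pl <- unclass(cfg$params)
  header <- c(
    sprintf("# fatecircuit %s",
            as.character(utils::packageVersion("fatecircuit"))),
    sprintf("# analysis: %s | model: %s | seed: %d",
            cfg$analysis, cfg$model_type, cfg$seed),
    sprintf("# params: %s",
            paste(sprintf("%s=%g", names(pl), unlist(pl)), collapse = " "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(tbl), con, row.names = FALSE)
  invisible(path)
}

#' Paths of the shipped preset configurations
#'
#' Presets covering the regimes analysed in the package: a full bifurcation
#' sweep, the monostable (`q = 0.5`) and bistable (`q = 2`) noisy regimes,
#' and the degenerate `b = c` case in two parameterizations (`b = 0.5` with
#' manifold range `[0, 2]`, and `b = 1` with range `[0, 1]`).
#'
#' @param name Optional preset name; without it, all preset paths.
#' @return File path(s) to YAML presets under the installed package.
#' @export
preset_config <- function(name = NULL) {
  dir <- system.file("presets", package = "fatecircuit")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  if (is.null(name)) return(files)
  hit <- files[tools::file_path_sans_ext(basename(files)) == name]
  if (length(hit) != 1L) {
    stop("unknown preset: ", name, " (available: ",
         paste(tools::file_path_sans_ext(basename(files)), collapse = ", "),
         ")", call. = FALSE)
  }
  hit
}
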