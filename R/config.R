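#' Run configuration
#'
#' The canonical on-disk configuration dialect is JSON (one file describes a
#' whole run). Top-level keys, all optional except `model`:
#' `phantom` (the string `"prostate"` or a phantom-spec object), `beams`,
#' `kernel`, `model` (`"dv"`, `"geud"`, `"ntcp"`), `prescription` (the
#' string `"prostate"` or a constraint list + evaluation table), `solver`,
#' `loop`, `k0`, `steplength`, `seed`, `push_coverage`, `out_dir`. Unknown
#' keys are rejected (prescription typos silently change clinical
#' semantics, so the schema is strict).
#'
#' @param model objective model.
#' @param phantom phantom preset name or a [phantom_spec()].
#' @param beams a [beam_spec()].
#' @param kernel a [dose_kernel()].
#' @param prescription preset name or an `fmo_prescription`.
#' @param solver a [solver_config()].
#' @param loop a [loop_config()].
#' @param k0,steplength compensation schedule overrides (NULL = model default).
#' @param seed integer seed echoed into reports.
#' @param push_coverage logical, see [run_automatic()].
#' @param out_dir default output directory for [write_report()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(model, phantom = "prostate", beams = beam_spec(),
                       kernel = dose_kernel(), prescription = "prostate",
                       solver = solver_config(), loop = loop_config(),
                       k0 = NULL, steplength = NULL, seed = 1L,
                       push_coverage = FALSE, out_dir = ".") {
  model <- match.arg(model, c("dv", "geud", "ntcp"))
  structure(list(model = model, phantom = phantom, beams = beams,
                 kernel = kernel, prescription = prescription,
                 solver = solver, loop = loop, k0 = k0,
                 steplength = steplength, seed = as.integer(seed),
                 push_coverage = isTRUE(push_coverage), out_dir = out_dir),
            class = "run_config")
}

run_config_keys <- c("model", "phantom", "beams", "kernel", "prescription",
                     "solver", "loop", "k0", "steplength", "seed",
                     "push_coverage", "out_dir")

#' Read a run configuration from JSON
#'
#' Validates strictly: unknown keys raise an error naming the key, and every
#' nested section is rebuilt through its constructor so invariant violations
#' (e.g. a dose-volume level of 150%) fail fast with the offending field
#' named. Defaults are filled for any key not present.
#'
#' @param path JSON file path.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  unknown <- setdiff(names(raw), run_config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(raw$model)) stop("config key \"model\" is required", call. = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  cfg <- run_config(
    model = raw$model,
    phantom = parse_phantom_field(raw$phantom),
    beams = parse_section(raw$beams, beam_spec,
                          c("gantry_angles_deg", "beamlet_width", "field_margin_mm")),
    kernel = parse_section(raw$kernel, dose_kernel,
                           c("mu_attenuation", "sigma_penumbra", "floor_frac")),
    prescription = parse_prescription_field(raw$prescription),
    solver = parse_section(raw$solver, solver_config,
                           c("max_iters", "tol", "history_size")),
    loop = parse_section(raw$loop, loop_config,
                         c("inner_adjust_iters", "max_compensation_iters")),
    k0 = num(raw$k0), steplength = num(raw$steplength),
    seed = if (is.null(raw$seed)) 1L else raw$seed,
    push_coverage = isTRUE(raw$push_coverage),
    out_dir = raw$out_dir %||% "."
  )
  cfg
}

parse_section <- function(raw, constructor, allowed) {
  if (is.null(raw)) return(constructor())
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in config section: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(constructor, raw)
}

parse_phantom_field <- function(raw) {
  if (is.null(raw) || identical(raw, "prostate")) return("prostate")
  if (is.character(raw)) stop(sprintf("unknown phantom preset \"%s\"", raw), call. = FALSE)
  structures <- lapply(raw$structures, function(s) {
    s <- lapply(s, function(x) if (is.list(x)) unlist(x) else x)
    s
  })
  phantom_spec(grid_shape = unlist(raw$grid_shape),
               voxel_size = raw$voxel_size,
               structures = structures,
               seed = raw$seed %||% 1L,
               overlap_tol = raw$overlap_tol %||% 0)
}

constraint_from_list <- function(s) {
  s <- lapply(s, function(x) if (is.list(x)) unlist(x) else x)
  type <- s$type %||% stop("constraint missing \"type\"", call. = FALSE)
  args <- s[setdiff(names(s), "type")]
  fun <- switch(type,
    min_dose = constraint_min_dose, max_dose = constraint_max_dose,
    mean_dose = constraint_mean_dose, dv_max = constraint_dv_max,
    dv_min = constraint_dv_min, geud = constraint_geud,
    ntcp = constraint_ntcp, tcp = constraint_tcp,
    stop(sprintf("unknown constraint type \"%s\"", type), call. = FALSE)
  )
  do.call(fun, args)
}

parse_prescription_field <- function(raw) {
  if (is.null(raw) || identical(raw, "prostate")) return("prostate")
  if (is.character(raw)) {
    stop(sprintf("unknown prescription preset \"%s\"", raw), call. = FALSE)
  }
  tab <- function(x) if (is.null(x)) NULL else dplyr::bind_rows(lapply(x, tibble::as_tibble))
  prescription(
    constraints = lapply(raw$constraints, constraint_from_list),
    ptv_coverage_pct = raw$ptv_coverage_pct %||% 95,
    evaluation = tab(raw$evaluation),
    guidelines = tab(raw$guidelines)
  )
}

#' Write a run configuration to JSON
#'
#' The file round-trips: `load_run_config(save_run_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- list(
    model = config$model,
    phantom = if (is.character(config$phantom)) config$phantom else {
      sp <- config$phantom
      list(grid_shape = sp$grid_shape, voxel_size = sp$voxel_size,
           structures = lapply(sp$structures, function(s) s),
           seed = sp$seed, overlap_tol = sp$overlap_tol)
    },
    beams = unclass(config$beams)[c("gantry_angles_deg", "beamlet_width",
                                    "field_margin_mm")],
    kernel = config$kernel,
    prescription = if (is.character(config$prescription)) config$prescription else {
      p <- config$prescription
      list(constraints = lapply(p$constraints, function(con)
             unclass(con)[setdiff(names(con), "evaluator")]),
           ptv_coverage_pct = p$ptv_coverage_pct,
           evaluation = lapply(seq_len(nrow(p$evaluation)),
                               function(i) as.list(p$evaluation[i, ])),
           guidelines = lapply(seq_len(nrow(p$guidelines)),
                               function(i) as.list(p$guidelines[i, ])))
    },
    solver = unclass(config$solver),
    loop = unclass(config$loop),
    seed = config$seed,
    push_coverage = config$push_coverage,
    out_dir = config$out_dir
  )
  if (!is.null(config$k0)) ser$k0 <- config$k0
  if (!is.null(config$steplength)) ser$steplength <- config$steplength
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Materialize and execute a configured run
#'
#' Resolves presets, builds the phantom and influence matrix, and calls
#' [run_automatic()].
#'
#' @param config a `run_config` (or a path to one on disk).
#' @return An `autofmo_run`.
#' @export
execute_run <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  spec <- if (is.character(config$phantom)) default_prostate_spec() else config$phantom
  presc <- if (is.character(config$prescription)) default_prostate_prescription()
           else config$prescription
  phantom <- generate_phantom(spec)
  im <- compute_influence_matrix(phantom, config$beams, config$kernel)
  set.seed(config$seed)
  run_automatic(phantom, im, presc, model = config$model,
                loop = config$loop, solver = config$solver,
                k0 = config$k0, steplength = config$steplength,
                push_coverage = config$push_coverage)
}
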