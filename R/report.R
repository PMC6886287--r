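#' Write the standard report files for a completed run
#'
#' Writes, with fixed file names, everything needed to redraw the run:
#' * `dvh.csv` — cumulative DVH samples for every structure
#'   (`structure`, `dose_Gy`, `volume_pct`);
#' * `metrics.csv` — one row per structure with dose statistics, CI and HI
#'   on the PTV row, and gEUD/NTCP where parameters are known;
#' * `weights_history.csv` — one row per (outer iteration, subscore) with
#'   the importance factor, correction factor and subscore value, enough to
#'   redraw an importance-factor trajectory;
#' * `solver_trace.csv` — objective value per inner-solver evaluation of the
#'   final solve;
#' * `plan_report.json` — metrics, evaluation outcome, final weights,
#'   compensation coefficient and acceptance flag;
#' * `config.json` — echo of the run configuration, when one is supplied.
#'
#' @param run an `autofmo_run`.
#' @param out_dir output directory (created if missing).
#' @param config optional `run_config` to echo.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_report <- function(run, out_dir, config = NULL) {
  stopifnot(inherits(run, "autofmo_run"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
  }
  phantom <- run$phantom
  dose <- run$plan$dose

  dvh_tbl <- purrr::map_dfr(names(phantom$masks), function(nm) {
    dvh(dose, phantom$masks[[nm]], structure = nm)
  })
  dvh_path <- file.path(out_dir, "dvh.csv")
  readr::write_csv(dvh_tbl, dvh_path)

  ptv_con <- ptv_min_constraint(run$prescription)
  biology <- plan_biology(run$prescription)
  metrics <- plan_metrics(dose, phantom, ref_dose = ptv_con$d_min, biology = biology)
  metrics_path <- file.path(out_dir, "metrics.csv")
  readr::write_csv(metrics, metrics_path)

  wh <- tidy(run)
  wh_path <- file.path(out_dir, "weights_history.csv")
  readr::write_csv(wh, wh_path)

  trace_path <- file.path(out_dir, "solver_trace.csv")
  readr::write_csv(run$plan$trace, trace_path)

  report <- list(
    model = run$model,
    accepted = run$accepted,
    k_final = run$k_final,
    n_solves = run$n_solves,
    objective = run$plan$objective,
    subscores = run$plan$subscores,
    final_weights = run$plan$weights,
    ptv_coverage_pct = run$evaluation$ptv_coverage_pct,
    criteria = lapply(seq_len(nrow(run$evaluation$criteria)), function(i)
      as.list(run$evaluation$criteria[i, ])),
    guidelines = lapply(seq_len(nrow(run$evaluation$guidelines)), function(i)
      as.list(run$evaluation$guidelines[i, ])),
    metrics = lapply(seq_len(nrow(metrics)), function(i) as.list(metrics[i, ]))
  )
  report_path <- file.path(out_dir, "plan_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)

  files <- c(dvh = dvh_path, metrics = metrics_path, weights = wh_path,
             trace = trace_path, report = report_path)
  if (!is.null(config)) {
    cfg_path <- file.path(out_dir, "config.json")
    save_run_config(config, cfg_path)
    files <- c(files, config = cfg_path)
  }
  invisible(files)
}

# gEUD/NTCP parameter sets per structure, harvested from the prescription
plan_biology <- function(prescription) {
  bio <- list()
  for (con in prescription$constraints) {
    if (con$type == "geud") {
      bio[[con$structure]] <- utils::modifyList(bio[[con$structure]] %||% list(),
                                                list(a = con$a))
    } else if (con$type == "ntcp") {
      bio[[con$structure]] <- utils::modifyList(
        bio[[con$structure]] %||% list(),
        list(td50 = con$td50, m = con$m, n = con$n,
             a = (bio[[con$structure]]$a) %||% (1 / con$n)))
    }
  }
  bio
}
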