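#' Tidy the outer-loop history of an automatic run
#'
#' One row per (outer iteration, subscore): the importance factor in force
#' during the solve, the correction factor computed from its result, the
#' subscore value, and the compensation bookkeeping. This long table is what
#' `weights_history.csv` contains and is sufficient to redraw an
#' importance-factor trajectory across the run.
#'
#' @param x an `autofmo_run`.
#' @param ... unused.
#' @return A tibble with columns `outer_iter`, `stage`, `comp_iter`, `iter`,
#'   `k`, `subscore`, `structure`, `type`, `weight`, `factor`, `value`,
#'   `objective`.
#' @method tidy autofmo_run
#' @export
tidy.autofmo_run <- function(x, ...) {
  h <- x$history
  labels <- purrr::map_chr(x$spec$subscores, function(s)
    paste0(s$constraint$type, ":", s$structure))
  structures <- purrr::map_chr(x$spec$subscores, "structure")
  types <- purrr::map_chr(x$spec$subscores, function(s) s$constraint$type)
  purrr::map_dfr(seq_len(nrow(h)), function(i) {
    tibble::tibble(
      outer_iter = i,
      stage = h$stage[i], comp_iter = h$comp_iter[i], iter = h$iter[i],
      k = h$k[i],
      subscore = seq_along(labels), label = labels,
      structure = structures, type = types,
      weight = h$weights[[i]], factor = h$factors[[i]],
      value = h$subscores[[i]],
      objective = h$objective[i]
    )
  })
}

#' One-row summary of an automatic run
#'
#' @param x an `autofmo_run`.
#' @param ... unused.
#' @return A one-row tibble: `model`, `accepted`, `n_solves`, `k_final`,
#'   `objective`, `ptv_coverage_pct`, `n_criteria_met`, `n_criteria`,
#'   `CI`, `HI`.
#' @method glance autofmo_run
#' @export
glance.autofmo_run <- function(x, ...) {
  ptv_con <- ptv_min_constraint(x$prescription)
  ptv_mask <- structure_mask(x$phantom, name = ptv_con$structure)
  body_mask <- structure_mask(x$phantom, role = "body")
  tibble::tibble(
    model = x$model, accepted = x$accepted, n_solves = x$n_solves,
    k_final = x$k_final, objective = x$plan$objective,
    ptv_coverage_pct = x$evaluation$ptv_coverage_pct,
    n_criteria_met = sum(x$evaluation$criteria$satisfied),
    n_criteria = nrow(x$evaluation$criteria),
    CI = conformity_index(x$plan$dose, ptv_mask, body_mask, ptv_con$d_min),
    HI = if (sum(ptv_mask) >= 20) homogeneity_index(x$plan$dose, ptv_mask) else NA_real_
  )
}

#' Tidy a single fluence-map plan
#'
#' @param x an `fmo_plan`.
#' @param ... unused.
#' @return A tibble with one row per subscore: `subscore`, `weight`,
#'   `value`, `weighted` (contribution to the total objective).
#' @method tidy fmo_plan
#' @export
tidy.fmo_plan <- function(x, ...) {
  tibble::tibble(subscore = seq_along(x$subscores), weight = x$weights,
                 value = x$subscores, weighted = x$weights * x$subscores)
}

#' One-row summary of a fluence-map plan
#'
#' @param x an `fmo_plan`.
#' @param ... unused.
#' @return A one-row tibble: `objective`, `n_beamlets`, `max_weight`,
#'   `n_evals`, `convergence`.
#' @method glance fmo_plan
#' @export
glance.fmo_plan <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_beamlets = length(x$x),
                 max_weight = max(x$x), n_evals = x$convergence$n_evals,
                 convergence = x$convergence$code)
}
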