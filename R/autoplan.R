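#' Outer-loop configuration
#'
#' @param inner_adjust_iters number of weight-adjustment iterations per pass
#'   (each = one inner FMO solve followed by one weight update; default 5).
#' @param max_compensation_iters maximum number of compensation iterations
#'   (default 10).
#' @return A list of class `loop_config`.
#' @export
loop_config <- function(inner_adjust_iters = 5, max_compensation_iters = 10) {
  stopifnot(inner_adjust_iters > 0, max_compensation_iters > 0)
  structure(list(inner_adjust_iters = as.integer(inner_adjust_iters),
                 max_compensation_iters = as.integer(max_compensation_iters)),
            class = "loop_config")
}

#' Prescription-value-based weight-correction factor
#'
#' The multiplicative pressure applied to a subscore's importance factor,
#' computed from the ratio of the current plan value to the prescribed
#' value. The ratio direction is chosen per constraint type so that a
#' violated constraint always yields a factor > 1 (more weight) and an
#' over-satisfied one a factor < 1:
#'
#' | constraint | factor |
#' |---|---|
#' | minimum dose | `d_min_pre / d_min_cur` |
#' | maximum dose | `d_max_cur / d_max_pre` |
#' | mean dose (PTV) | `max(cur, pre) / min(cur, pre)` |
#' | mean dose (OAR) | `d_mean_cur / d_mean_pre` |
#' | max dose-volume | `V2 / V1` (current vs prescribed volume at `D1`) |
#' | min dose-volume | `V1 / V2` |
#' | gEUD (OAR, a >= 1) | `gEUD_cur / gEUD_pre` |
#' | gEUD (PTV, a < 1) | `gEUD_pre / gEUD_cur` |
#' | NTCP | `NTCP_cur / NTCP_pre` |
#' | TCP | `TCP_pre / TCP_cur` |
#'
#' Factors are clamped to `[0.01, 100]`; a zero denominator (e.g. a cold
#' start with zero dose) yields the clamp ceiling with a warning rather
#' than an error.
#'
#' @param constraint an [constraints] record.
#' @param d dose vector over the constraint's structure (Gy).
#' @return A positive scalar factor.
#' @export
correction_factor <- function(constraint, d) {
  con <- constraint
  ratio <- switch(con$type,
    min_dose = con$d_min / min(d),
    max_dose = max(d) / con$d_max,
    mean_dose = {
      cur <- mean(d)
      if (con$role == "ptv") max(cur, con$d_mean) / min(cur, con$d_mean)
      else cur / con$d_mean
    },
    dv_max = {
      v2 <- 100 * mean(d >= con$d1)
      v2 / con$v1
    },
    dv_min = {
      v2 <- 100 * mean(d >= con$d1)
      con$v1 / v2
    },
    geud = {
      g <- geud(d, seq_along(d), con$a)
      if (con$a >= 1) g / con$geud_pre else con$geud_pre / g
    },
    ntcp = ntcp_lkb(d, seq_along(d), con$td50, con$m, con$n) / con$ntcp_pre,
    tcp = con$tcp_pre / con$evaluator(d),
    stop(sprintf("unknown constraint type \"%s\"", con$type), call. = FALSE)
  )
  clamp_factor(ratio)
}

clamp_factor <- function(ratio, lo = 0.01, hi = 100) {
  if (!is.finite(ratio) || ratio <= 0) {
    if (!is.finite(ratio)) {
      warning("degenerate correction-factor ratio; clamped to ceiling", call. = FALSE)
      return(hi)
    }
    return(lo)
  }
  min(max(ratio, lo), hi)
}

#' Correction factors for every subscore of an objective
#'
#' @param spec an [objective_spec()].
#' @param dose voxel dose vector of the current plan (Gy).
#' @return Numeric vector of factors, one per subscore.
#' @export
correction_factors <- function(spec, dose) {
  vapply(spec$subscores,
         function(s) correction_factor(s$constraint, dose[s$voxels]),
         numeric(1))
}

#' Additive importance-factor update with normalization
#'
#' `w_new = w_old + k * factor`, componentwise, followed by normalization to
#' sum 1 so all importance factors stay within (0, 1). Outside the
#' compensation stage `k = 1` for every subscore; during compensation the
#' targeted subscores carry the current compensation coefficient.
#'
#' @param w importance-factor vector (positive, any scale).
#' @param factors correction factors, one per subscore.
#' @param k compensation coefficient: scalar or per-subscore vector.
#' @return Normalized importance-factor vector (sums to 1).
#' @export
update_weights <- function(w, factors, k = 1) {
  if (length(w) != length(factors)) {
    stop("`w` and `factors` lengths differ", call. = FALSE)
  }
  w_new <- w + k * factors
  w_new / sum(w_new)
}

#' Evaluate a plan against its prescription
#'
#' Two acceptability checks gate the loop: (i) PTV coverage — the volume of
#' the PTV receiving the prescribed minimum dose must reach the coverage
#' threshold (default 95%); (ii) every rule of the prescription's evaluation
#' table (by default its own maximum dose-volume constraints) must hold,
#' `V(D1) <= V1`. The prescription's clinical guideline table, if any, is
#' additionally reported (strict `<`) but does not gate acceptance. When
#' the plan is unacceptable, compensation targets are selected: all PTV
#' subscores if coverage fails; otherwise the subscore linked to the
#' violated evaluation rule with the highest dose level (the high-dose
#' region of the OAR is considered first).
#'
#' @param dose voxel dose vector of the plan (Gy).
#' @param phantom a `phantom`.
#' @param prescription an `fmo_prescription`.
#' @param spec the [objective_spec()] in use (supplies the subscore indices
#'   that compensation targets refer to).
#' @return A list of class `plan_evaluation`: `ptv_coverage_pct`,
#'   `ptv_satisfied`, `criteria` (tibble with per-rule `value_pct` and
#'   `satisfied`), `guidelines` (same shape, strict `<`, reporting only),
#'   `all_satisfied`, `compensation_targets` (integer subscore indices,
#'   empty iff acceptable).
#' @export
evaluate_plan <- function(dose, phantom, prescription, spec) {
  ptv_con <- ptv_min_constraint(prescription)
  ptv_mask <- structure_mask(phantom, name = ptv_con$structure)
  coverage <- volume_at_dose(dose, ptv_mask, ptv_con$d_min)
  ptv_ok <- coverage >= prescription$ptv_coverage_pct

  check_rules <- function(rules, strict) {
    dplyr::mutate(
      rules,
      value_pct = purrr::map2_dbl(.data$structure, .data$dose_Gy, function(s, dd) {
        volume_at_dose(dose, structure_mask(phantom, name = s), dd)
      }),
      satisfied = if (strict) .data$value_pct < .data$volume_pct
                  else .data$value_pct <= .data$volume_pct
    )
  }
  crit <- check_rules(prescription$evaluation, strict = FALSE)
  guide <- check_rules(prescription$guidelines, strict = TRUE)
  all_ok <- ptv_ok && all(crit$satisfied)

  targets <- integer(0)
  if (!ptv_ok) {
    targets <- which(vapply(spec$subscores, function(s)
      s$role_in_objective == "ptv_coverage", logical(1)))
  } else if (!all(crit$satisfied)) {
    viol <- crit[!crit$satisfied, ]
    viol <- viol[order(-viol$dose_Gy), ]
    for (r in seq_len(nrow(viol))) {
      targets <- match_criterion_subscore(spec, viol$structure[r], viol$dose_Gy[r])
      if (length(targets)) break
    }
  }
  structure(list(ptv_coverage_pct = coverage, ptv_satisfied = ptv_ok,
                 criteria = crit, guidelines = guide,
                 all_satisfied = all_ok,
                 compensation_targets = targets),
            class = "plan_evaluation")
}

# Map a violated dose-volume guideline (structure, dose level) to the
# subscore that controls it. For dv surrogates, the one with the largest
# D1 at or below the guideline dose (pushing V(D1) down also drags the
# volume at any higher dose level); when every D1 lies above the guideline
# dose, the lowest D1. Non-dv models use the structure's single OAR
# subscore.
match_criterion_subscore <- function(spec, structure, dose_Gy) {
  on_struct <- which(vapply(spec$subscores, function(s)
    s$structure == structure, logical(1)))
  if (!length(on_struct)) return(integer(0))
  dv <- on_struct[vapply(spec$subscores[on_struct], function(s)
    s$constraint$type == "dv_max", logical(1))]
  if (length(dv)) {
    d1 <- vapply(spec$subscores[dv], function(s) s$constraint$d1, numeric(1))
    below <- d1 <= dose_Gy
    if (any(below)) return(dv[below][which.max(d1[below])])
    return(dv[which.min(d1)])
  }
  on_struct[1]
}

#' @export
print.plan_evaluation <- function(x, ...) {
  cat(sprintf("<plan_evaluation> PTV coverage %.1f%% (%s); %d/%d DV rules met; %s\n",
              x$ptv_coverage_pct, if (x$ptv_satisfied) "ok" else "FAIL",
              sum(x$criteria$satisfied), nrow(x$criteria),
              if (x$all_satisfied) "acceptable" else "not acceptable"))
  if (nrow(x$guidelines)) {
    cat(sprintf("  clinical guidelines: %d/%d met\n",
                sum(x$guidelines$satisfied), nrow(x$guidelines)))
  }
  invisible(x)
}

model_compensation_defaults <- function(model) {
  switch(model,
    dv = list(k0 = 1, steplength = 1),
    geud = list(k0 = 10, steplength = 5),
    ntcp = list(k0 = 1, steplength = 1),
    stop(sprintf("unknown model \"%s\"", model), call. = FALSE)
  )
}

#' Automatic importance-factor optimization
#'
#' Runs the full automatic planning loop. Stage I (iterative adjustment):
#' starting from uniform importance factors, alternate an inner FMO solve
#' with a prescription-value-based weight update, `inner_adjust_iters`
#' times, then evaluate the plan. If it is unacceptable, the compensation
#' stage multiplies the correction factors of the targeted subscores by a
#' coefficient `k` that grows on an arithmetic schedule
#' (`k = k0 + (iter - 1) * steplength`), rerunning Stage I after each
#' increase, until the plan is acceptable or `max_compensation_iters` is
#' exhausted. Targets are re-selected from the most recent evaluation (PTV
#' subscores when coverage fails; otherwise the highest-dose violated OAR
#' guideline's subscore). If no plan becomes acceptable the best evaluated
#' plan is returned, flagged unacceptable; "best" is lexicographic on
#' (PTV satisfied, number of satisfied guidelines, lower objective).
#'
#' @param phantom a `phantom`.
#' @param im the `influence_matrix` for `phantom`.
#' @param prescription an `fmo_prescription`.
#' @param model objective model: `"dv"`, `"geud"` or `"ntcp"`.
#' @param loop a [loop_config()].
#' @param solver a [solver_config()].
#' @param k0,steplength compensation schedule; defaults depend on the model:
#'   (1, 1) for `dv`, (10, 5) for `geud`, (1, 1) for `ntcp`.
#' @param weights0 initial importance factors (default uniform `1/l`); any
#'   positive vector is normalized.
#' @param push_coverage optional post-pass: after an acceptable plan is
#'   found, keep adjusting while every criterion stays satisfied, returning
#'   the last acceptable plan (off by default).
#' @return An object of class `autofmo_run`: final `plan` (`fmo_plan`),
#'   `evaluation`, `accepted` flag, `history` tibble (one row per outer
#'   iteration: stage, compensation iteration, `k`, objective, subscores,
#'   weights and factors as list-columns), `k_final`, `n_solves`, plus the
#'   `spec`, `prescription`, `model` and configs used.
#' @export
run_automatic <- function(phantom, im, prescription, model = c("dv", "geud", "ntcp"),
                          loop = loop_config(), solver = solver_config(),
                          k0 = NULL, steplength = NULL, weights0 = NULL,
                          push_coverage = FALSE) {
  model <- match.arg(model)
  comp <- model_compensation_defaults(model)
  if (is.null(k0)) k0 <- comp$k0
  if (is.null(steplength)) steplength <- comp$steplength
  spec <- objective_spec(prescription, phantom, model)
  l <- spec$n_subscores
  if (is.null(weights0)) weights0 <- rep(1 / l, l)
  stopifnot(length(weights0) == l, all(weights0 > 0))
  weights0 <- weights0 / sum(weights0)

  ptv_con <- ptv_min_constraint(prescription)
  d_mean_target <- {
    dm <- NULL
    for (con in prescription$constraints) {
      if (con$type == "mean_dose" && con$role == "ptv") dm <- con$d_mean
    }
    dm %||% ptv_con$d_min
  }
  x_init <- initial_fluence(im, structure_mask(phantom, name = ptv_con$structure),
                            d_mean_target)

  history <- list()
  n_solves <- 0L

  stage_one <- function(k_vec, stage, comp_iter, k_value) {
    w <- weights0
    x <- x_init
    plan <- NULL
    for (it in seq_len(loop$inner_adjust_iters)) {
      plan <- solve_fmo(im, spec, w, x, solver)
      n_solves <<- n_solves + 1L
      factors <- correction_factors(spec, plan$dose)
      history[[length(history) + 1L]] <<- tibble::tibble(
        stage = stage, comp_iter = comp_iter, iter = it, k = k_value,
        objective = plan$objective,
        weights = list(w), factors = list(factors),
        subscores = list(plan$subscores)
      )
      w <- update_weights(w, factors, k_vec)
      x <- plan$x
    }
    plan
  }

  score_eval <- function(ev, plan) {
    c(as.numeric(ev$ptv_satisfied), sum(ev$criteria$satisfied), -plan$objective)
  }
  better <- function(a, b) {       # TRUE if score a beats b
    for (i in seq_along(a)) {
      if (a[i] > b[i]) return(TRUE)
      if (a[i] < b[i]) return(FALSE)
    }
    FALSE
  }

  plan <- stage_one(rep(1, l), "adjust", 0L, NA_real_)
  ev <- evaluate_plan(plan$dose, phantom, prescription, spec)
  best <- list(plan = plan, ev = ev, score = score_eval(ev, plan), k = NA_real_)
  k_final <- NA_real_

  if (!ev$all_satisfied) {
    for (ci in seq_len(loop$max_compensation_iters)) {
      k <- k0 + (ci - 1) * steplength
      k_vec <- rep(1, l)
      k_vec[ev$compensation_targets] <- k
      plan <- stage_one(k_vec, "compensation", ci, k)
      ev <- evaluate_plan(plan$dose, phantom, prescription, spec)
      k_final <- k
      sc <- score_eval(ev, plan)
      if (better(sc, best$score)) best <- list(plan = plan, ev = ev, score = sc, k = k)
      if (ev$all_satisfied) break
    }
    if (!ev$all_satisfied) {
      plan <- best$plan
      ev <- best$ev
    }
  }

  if (push_coverage && ev$all_satisfied) {
    # keep adjusting while everything stays satisfied; keep last acceptable plan
    w <- plan$weights
    x <- plan$x
    for (it in seq_len(loop$inner_adjust_iters)) {
      factors <- correction_factors(spec, plan$dose)
      w <- update_weights(w, factors, 1)
      cand <- solve_fmo(im, spec, w, x, solver)
      n_solves <- n_solves + 1L
      ev_cand <- evaluate_plan(cand$dose, phantom, prescription, spec)
      if (!ev_cand$all_satisfied) break
      plan <- cand
      ev <- ev_cand
      x <- cand$x
      history[[length(history) + 1L]] <- tibble::tibble(
        stage = "push_coverage", comp_iter = 0L, iter = it, k = NA_real_,
        objective = cand$objective, weights = list(w),
        factors = list(factors), subscores = list(cand$subscores)
      )
    }
  }

  structure(
    list(plan = plan, evaluation = ev, accepted = ev$all_satisfied,
         history = dplyr::bind_rows(history),
         k_final = k_final, n_solves = n_solves,
         spec = spec, prescription = prescription, model = model,
         loop = loop, solver = solver, k0 = k0, steplength = steplength,
         phantom = phantom),
    class = "autofmo_run"
  )
}

#' @export
print.autofmo_run <- function(x, ...) {
  cat(sprintf("<autofmo_run> model=%s: %s after %d inner solves%s\n",
              x$model,
              if (x$accepted) "acceptable plan" else "budget exhausted (best plan returned)",
              x$n_solves,
              if (is.na(x$k_final)) "" else sprintf(", final k = %g", x$k_final)))
  print(x$evaluation)
  invisible(x)
}
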