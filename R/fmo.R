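#' Inner-solver configuration
#'
#' @param max_iters L-BFGS iteration cap per inner solve (default 50).
#' @param tol convergence tolerance on the relative objective change
#'   (default 1e-6); mapped onto the solver's `factr` control.
#' @param history_size number of curvature pairs kept by L-BFGS.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(max_iters = 50, tol = 1e-6, history_size = 10) {
  stopifnot(max_iters > 0, tol > 0, history_size > 0)
  structure(list(max_iters = as.integer(max_iters), tol = tol,
                 history_size = as.integer(history_size)),
            class = "solver_config")
}

#' Cold-start fluence
#'
#' A uniform positive beamlet-weight vector scaled by a scalar least-squares
#' fit so the mean PTV dose equals the prescribed PTV mean dose. A strictly
#' positive start matters: under the square-root parameterization `x = u^2`
#' the point `u = 0` is stationary, so an all-zero start makes no progress.
#'
#' @param im an `influence_matrix`.
#' @param ptv_mask logical PTV mask (or voxel indices).
#' @param d_mean target mean PTV dose in Gy.
#' @return Beamlet weight vector, all entries equal and positive.
#' @export
initial_fluence <- function(im, ptv_mask, d_mean) {
  stopifnot(inherits(im, "influence_matrix"), d_mean > 0)
  idx <- if (is.logical(ptv_mask)) which(ptv_mask) else as.integer(ptv_mask)
  per_unit <- mean(as.numeric(im$A[idx, , drop = FALSE] %*%
                                rep(1, ncol(im$A))))
  if (per_unit <= 0) stop("no beamlet covers the PTV", call. = FALSE)
  rep(d_mean / per_unit, ncol(im$A))
}

#' Solve the fluence-map optimization problem
#'
#' Minimizes the weighted objective over beamlet weights using L-BFGS on the
#' square-root variables `u` (`x = u^2`), which keeps the weights
#' nonnegative without box constraints. The `D2` levels of dose-volume
#' surrogate subscores are recomputed from the current dose at every
#' objective evaluation (dynamic windows); this keeps the surrogate penalty
#' continuous, because the penalty window then changes only by swapping
#' voxels of equal dose at the quantile boundary. The gradient treats the
#' window as locally constant, which is exact almost everywhere.
#'
#' @param im an `influence_matrix`.
#' @param spec an [objective_spec()].
#' @param weights importance-factor vector, normalized to sum 1.
#' @param x0 starting beamlet weights, all >= 0.
#' @param config a [solver_config()].
#' @return An object of class `fmo_plan`: beamlet weights `x`, `dose`,
#'   total `objective`, per-subscore values `subscores`, the final `d2`
#'   levels, the `weights` used, solver `trace` (tibble of objective
#'   evaluations) and `convergence` info.
#' @export
solve_fmo <- function(im, spec, weights, x0, config = solver_config()) {
  stopifnot(inherits(im, "influence_matrix"), inherits(spec, "objective_spec"))
  if (length(weights) != spec$n_subscores) {
    stop("`weights` length must match the number of subscores", call. = FALSE)
  }
  if (any(x0 < 0)) stop("starting weights must be nonnegative", call. = FALSE)
  u0 <- sqrt(x0)

  trace_obj <- new.env(parent = emptyenv())
  trace_obj$f <- numeric(0)

  fn <- function(u) {
    dose <- compute_dose(im, u^2)
    ev <- eval_objective(spec, dose, weights)
    val <- total_objective(ev$f, weights)
    if (!is.finite(val)) {
      stop(sprintf("non-finite objective (value %s); |u| max = %.3g",
                   format(val), max(abs(u))), call. = FALSE)
    }
    trace_obj$f <- c(trace_obj$f, val)
    val
  }
  gr <- function(u) {
    dose <- compute_dose(im, u^2)
    ev <- eval_objective(spec, dose, weights, gradient = TRUE)
    g <- 2 * u * as.numeric(Matrix::crossprod(im$A, ev$grad_dose))
    if (any(!is.finite(g))) stop("non-finite gradient", call. = FALSE)
    g
  }
  f0 <- fn(u0)
  opt <- stats::optim(u0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_iters,
                                     factr = config$tol / .Machine$double.eps,
                                     lmm = config$history_size))
  # monotone safeguard: never return an iterate worse than the start
  if (opt$value > f0) {
    opt$par <- u0
    opt$value <- f0
  }
  x <- opt$par^2
  dose <- compute_dose(im, x)
  ev <- eval_objective(spec, dose, weights)
  structure(
    list(x = x, u = opt$par, dose = dose,
         objective = total_objective(ev$f, weights),
         subscores = ev$f, d2 = ev$d2, weights = weights,
         trace = tibble::tibble(eval = seq_along(trace_obj$f),
                                objective = trace_obj$f),
         convergence = list(code = opt$convergence,
                            message = opt$message,
                            n_evals = unname(opt$counts[1]))),
    class = "fmo_plan"
  )
}

#' @export
print.fmo_plan <- function(x, ...) {
  cat(sprintf("<fmo_plan> %d beamlets, objective %.6g\n", length(x$x), x$objective))
  cat("  subscores:", paste(sprintf("%.4g", x$subscores), collapse = ", "), "\n")
  invisible(x)
}
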