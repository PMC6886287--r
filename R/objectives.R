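#' Prescription constraints
#'
#' Constructors for the typed constraint records a prescription is built
#' from. Each maps to one subscore in the planning objective and to one row
#' of the weight-correction table used by the automatic loop.
#'
#' @param structure structure name the constraint applies to.
#' @param role `"ptv"` or `"oar"`; decides the PTV/OAR variants of the
#'   mean-dose and gEUD correction factors.
#' @param d_min,d_max,d_mean dose levels in Gy.
#' @param d1 dose level of a dose-volume constraint (Gy).
#' @param v1 volume level of a dose-volume constraint, percent in (0, 100).
#' @param geud_pre prescribed gEUD in Gy.
#' @param a gEUD exponent (>= 1 for OAR constraints, < 1 for PTV use).
#' @param ntcp_pre prescribed complication probability in (0, 1).
#' @param td50,m,n LKB model parameters (see [ntcp_lkb()]).
#' @param tcp_pre prescribed tumor control probability in (0, 1).
#' @param evaluator for `constraint_tcp()`: a function `dose_structure ->
#'   probability` supplied by the user; no TCP model ships with the package.
#' @return A list of class `fmo_constraint`.
#' @name constraints
NULL

new_constraint <- function(type, structure, role, params) {
  structure(c(list(type = type, structure = structure, role = role), params),
            class = "fmo_constraint")
}

#' @rdname constraints
#' @export
constraint_min_dose <- function(structure, d_min, role = "ptv") {
  stopifnot(d_min > 0)
  new_constraint("min_dose", structure, role, list(d_min = d_min))
}

#' @rdname constraints
#' @export
constraint_max_dose <- function(structure, d_max, role = "oar") {
  stopifnot(d_max > 0)
  new_constraint("max_dose", structure, role, list(d_max = d_max))
}

#' @rdname constraints
#' @export
constraint_mean_dose <- function(structure, d_mean, role = "ptv") {
  stopifnot(d_mean > 0)
  new_constraint("mean_dose", structure, role, list(d_mean = d_mean))
}

#' @rdname constraints
#' @export
constraint_dv_max <- function(structure, d1, v1, role = "oar") {
  stopifnot(d1 > 0, v1 > 0, v1 < 100)
  new_constraint("dv_max", structure, role, list(d1 = d1, v1 = v1))
}

#' @rdname constraints
#' @export
constraint_dv_min <- function(structure, d1, v1, role = "ptv") {
  stopifnot(d1 > 0, v1 > 0, v1 < 100)
  new_constraint("dv_min", structure, role, list(d1 = d1, v1 = v1))
}

#' @rdname constraints
#' @export
constraint_geud <- function(structure, geud_pre, a, role = "oar") {
  stopifnot(geud_pre > 0, a != 0)
  new_constraint("geud", structure, role, list(geud_pre = geud_pre, a = a))
}

#' @rdname constraints
#' @export
constraint_ntcp <- function(structure, ntcp_pre, td50, m, n, role = "oar") {
  stopifnot(ntcp_pre > 0, ntcp_pre < 1, td50 > 0, m > 0, n > 0)
  new_constraint("ntcp", structure, role,
                 list(ntcp_pre = ntcp_pre, td50 = td50, m = m, n = n))
}

#' @rdname constraints
#' @export
constraint_tcp <- function(structure, tcp_pre, evaluator, role = "ptv") {
  stopifnot(tcp_pre > 0, tcp_pre < 1, is.function(evaluator))
  new_constraint("tcp", structure, role,
                 list(tcp_pre = tcp_pre, evaluator = evaluator))
}

#' @export
print.fmo_constraint <- function(x, ...) {
  pars <- setdiff(names(x), c("type", "structure", "role", "evaluator"))
  cat(sprintf("<constraint> %s on %s [%s]: %s\n", x$type, x$structure, x$role,
              paste(sprintf("%s=%.4g", pars, as.numeric(x[pars])), collapse = ", ")))
  invisible(x)
}

# ---- subscore primitives (all operate on the structure's dose vector) ------

#' Objective subscores
#'
#' The per-structure penalty functions combined by the weighted planning
#' objective. All use the strict step convention `H(x) = 1` iff `x > 0`, so a
#' constraint met with equality contributes no penalty.
#'
#' * `f_min()` — mean squared underdose below `d_min` (PTV cold spots).
#' * `f_mean()` — mean squared deviation from the prescribed mean dose.
#' * `f_dvmax()` — convex surrogate of a maximum dose-volume constraint:
#'   mean of `(D_i - d1)^2` over voxels with `d1 < D_i < d2`, where `d2` is
#'   the dose level whose hot volume equals the prescribed `v1`% in the
#'   current plan (see [compute_d2()]). When the constraint is already met
#'   (`d2 <= d1`) the penalty window is empty and the score is 0.
#' * `f_geud()` — linear overshoot of the structure gEUD above its
#'   prescription, `max(gEUD_cur - geud_pre, 0)`.
#' * `f_ntcp()` — logarithmic convex form of an NTCP constraint,
#'   `max(log(1 - ntcp_pre) - log(1 - NTCP_LKB), 0)`.
#'
#' @param d dose vector over the structure's voxels (Gy).
#' @param d_min,d_mean,d1,d2 dose levels in Gy.
#' @param geud_pre prescribed gEUD (Gy); `a` the gEUD exponent.
#' @param a gEUD exponent.
#' @param ntcp_pre prescribed NTCP; `td50`, `m`, `n` the LKB parameters.
#' @param td50,m,n LKB parameters.
#' @param cap value returned when the LKB NTCP is numerically 1 and the log
#'   penalty diverges.
#' @return A nonnegative scalar score.
#' @name subscores
NULL

#' @rdname subscores
#' @export
f_min <- function(d, d_min) {
  u <- d_min - d
  mean(ifelse(u > 0, u^2, 0))
}

#' @rdname subscores
#' @export
f_mean <- function(d, d_mean) {
  mean((d - d_mean)^2)
}

#' Current dose level at a prescribed hot volume
#'
#' `D2` of the convex dose-volume surrogate: the dose of descending rank
#' `ceiling(N * v1 / 100)` in the current plan, i.e. the level whose
#' hot-volume equals `v1`%. Refreshed once per inner solve, not per
#' optimizer step.
#'
#' @param d dose vector over the structure (Gy).
#' @param v1 volume percentage in (0, 100).
#' @return Dose in Gy.
#' @export
compute_d2 <- function(d, v1) {
  stopifnot(v1 > 0, v1 <= 100)
  sort(d, decreasing = TRUE)[ceiling(length(d) * v1 / 100)]
}

#' @rdname subscores
#' @export
f_dvmax <- function(d, d1, d2) {
  inside <- d > d1 & d < d2
  mean(ifelse(inside, (d - d1)^2, 0))
}

#' @rdname subscores
#' @export
f_geud <- function(d, geud_pre, a) {
  g <- geud(d, seq_along(d), a)
  max(g - geud_pre, 0)
}

#' @rdname subscores
#' @export
f_ntcp <- function(d, ntcp_pre, td50, m, n, cap = 1e6) {
  p <- ntcp_lkb(d, seq_along(d), td50, m, n)
  if (p >= 1 - 1e-15) {
    warning("LKB NTCP numerically 1; NTCP subscore capped", call. = FALSE)
    return(cap)
  }
  max(log(1 - ntcp_pre) - log(1 - p), 0)
}

#' Weighted total objective
#'
#' `f = sum_i w_i f_i` over the subscores of an objective specification.
#'
#' @param f numeric vector of subscore values.
#' @param w importance factors, same length.
#' @return Nonnegative scalar.
#' @export
total_objective <- function(f, w) {
  if (length(f) != length(w)) stop("`f` and `w` lengths differ", call. = FALSE)
  sum(w * f)
}

# ---- objective specification ----------------------------------------------

#' Assemble an objective specification from a prescription
#'
#' Builds the ordered subscore list of the chosen objective model from the
#' constraints of a prescription: every model carries the PTV minimum-dose
#' and PTV mean-dose subscores; the dose-volume model adds one surrogate
#' subscore per maximum dose-volume constraint, the gEUD model one linear
#' gEUD overshoot subscore per OAR, and the NTCP model one logarithmic LKB
#' subscore per OAR.
#'
#' @param prescription a [prescription()].
#' @param phantom a `phantom` supplying the structure masks.
#' @param model `"dv"`, `"geud"` or `"ntcp"`.
#' @return An object of class `objective_spec`: ordered subscores, each
#'   holding its constraint, structure voxel indices, and role.
#' @export
objective_spec <- function(prescription, phantom, model = c("dv", "geud", "ntcp")) {
  model <- match.arg(model)
  stopifnot(inherits(prescription, "fmo_prescription"), inherits(phantom, "phantom"))
  cons <- prescription$constraints
  types <- vapply(cons, `[[`, character(1), "type")
  ptv_name <- names(phantom$roles)[phantom$roles == "ptv"]

  pick <- function(keep) cons[keep]
  ptv_cons <- pick(types %in% c("min_dose", "mean_dose") &
                     vapply(cons, function(k) k$structure == ptv_name, logical(1)))
  # PTV min first, then PTV mean (objective ordering convention)
  ord <- order(match(vapply(ptv_cons, `[[`, character(1), "type"),
                     c("min_dose", "mean_dose")))
  ptv_cons <- ptv_cons[ord]
  if (!any(vapply(ptv_cons, `[[`, character(1), "type") == "min_dose")) {
    stop("prescription must contain a PTV minimum-dose constraint", call. = FALSE)
  }
  oar_cons <- switch(model,
    dv = pick(types %in% c("dv_max", "dv_min")),
    geud = pick(types == "geud"),
    ntcp = pick(types == "ntcp")
  )
  if (length(oar_cons) == 0) {
    stop(sprintf("prescription has no constraints for the \"%s\" model", model),
         call. = FALSE)
  }
  all_cons <- c(ptv_cons, oar_cons)
  subscores <- purrr::imap(unname(all_cons), function(con, i) {
    mask <- structure_mask(phantom, name = con$structure)
    list(index = i, constraint = con, structure = con$structure,
         role_in_objective = if (con$role == "ptv") "ptv_coverage" else "oar_sparing",
         voxels = which(mask))
  })
  structure(list(model = model, subscores = subscores,
                 n_subscores = length(subscores)),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("<objective_spec> model=%s, %d subscores\n", x$model, x$n_subscores))
  for (s in x$subscores) {
    cat(sprintf("  [%d] %s on %s\n", s$index, s$constraint$type, s$structure))
  }
  invisible(x)
}

# Refresh the D2 levels of all dv surrogate subscores for the current dose.
refresh_d2 <- function(spec, dose) {
  vapply(spec$subscores, function(s) {
    if (s$constraint$type %in% c("dv_max", "dv_min")) {
      compute_d2(dose[s$voxels], s$constraint$v1)
    } else NA_real_
  }, numeric(1))
}

# Evaluate all subscores and (optionally) the gradient of the weighted
# objective with respect to the voxel dose vector. `d2` holds the frozen
# per-subscore D2 levels. Returns list(f = per-subscore values,
# grad_dose = length-n_voxels vector or NULL).
eval_objective <- function(spec, dose, weights = NULL, d2 = NULL,
                           gradient = FALSE) {
  n <- length(dose)
  f <- numeric(spec$n_subscores)
  grad <- if (gradient) numeric(n) else NULL
  if (is.null(d2)) d2 <- refresh_d2(spec, dose)
  for (s in spec$subscores) {
    con <- s$constraint
    d <- dose[s$voxels]
    nv <- length(d)
    i <- s$index
    g_loc <- NULL
    if (con$type == "min_dose") {
      u <- con$d_min - d
      act <- u > 0
      f[i] <- sum(u[act]^2) / nv
      if (gradient) { g_loc <- numeric(nv); g_loc[act] <- -2 * u[act] / nv }
    } else if (con$type == "mean_dose") {
      f[i] <- mean((d - con$d_mean)^2)
      if (gradient) g_loc <- 2 * (d - con$d_mean) / nv
    } else if (con$type == "max_dose") {
      u <- d - con$d_max
      act <- u > 0
      f[i] <- sum(u[act]^2) / nv
      if (gradient) { g_loc <- numeric(nv); g_loc[act] <- 2 * u[act] / nv }
    } else if (con$type == "dv_max") {
      act <- d > con$d1 & d < d2[i]
      f[i] <- sum((d[act] - con$d1)^2) / nv
      if (gradient) { g_loc <- numeric(nv); g_loc[act] <- 2 * (d[act] - con$d1) / nv }
    } else if (con$type == "dv_min") {
      # cold-volume mirror of the dv_max surrogate: window [d2, d1]
      act <- d < con$d1 & d > d2[i]
      f[i] <- sum((d[act] - con$d1)^2) / nv
      if (gradient) { g_loc <- numeric(nv); g_loc[act] <- 2 * (d[act] - con$d1) / nv }
    } else if (con$type == "geud") {
      g <- geud(d, seq_len(nv), con$a)
      over <- g - con$geud_pre
      f[i] <- max(over, 0)
      if (gradient && over > 0 && g > 0) {
        g_loc <- geud_grad(d, con$a, g)
      } else if (gradient) g_loc <- numeric(nv)
    } else if (con$type == "ntcp") {
      g <- geud(d, seq_len(nv), 1 / con$n)
      t <- (g - con$td50) / (con$m * con$td50)
      p <- stats::pnorm(t)
      pen <- if (p >= 1 - 1e-15) 1e6 else log(1 - con$ntcp_pre) - log1p(-p)
      f[i] <- max(pen, 0)
      if (gradient) {
        if (pen > 0 && g > 0 && p < 1 - 1e-15) {
          dpen_dg <- stats::dnorm(t) / (con$m * con$td50) / (1 - p)
          g_loc <- dpen_dg * geud_grad(d, 1 / con$n, g)
        } else g_loc <- numeric(nv)
      }
    } else if (con$type == "tcp") {
      p <- con$evaluator(d)
      f[i] <- max(con$tcp_pre - p, 0)
      if (gradient) g_loc <- numeric(nv)   # user evaluators are not differentiated
    } else {
      stop(sprintf("unknown constraint type \"%s\"", con$type), call. = FALSE)
    }
    if (gradient && !is.null(weights)) grad[s$voxels] <- grad[s$voxels] + weights[i] * g_loc
  }
  list(f = f, grad_dose = grad, d2 = d2)
}

# d gEUD / d D_i = (1/N) * (D_i / gEUD)^(a-1); stable form scaled by gEUD.
geud_grad <- function(d, a, g) {
  (d / g)^(a - 1) / length(d)
}

#' Gradient of the weighted objective in square-root beamlet variables
#'
#' The inner solver optimizes `u` with beamlet weights `x = u^2`, so
#' `df/du_j = 2 u_j (A' df/dD)_j`. Quadratic subscores are differentiated
#' exactly; step-gated terms use their subgradient with the strict-step
#' convention; the gEUD and NTCP subscores are differentiated through the
#' power mean (and the normal CDF). `D2` levels of dose-volume surrogates
#' are treated as constants.
#'
#' @param spec an [objective_spec()].
#' @param weights importance-factor vector.
#' @param im an `influence_matrix`.
#' @param u square-root beamlet weight vector.
#' @param d2 frozen `D2` levels (defaults to refreshing them at `A u^2`).
#' @return Gradient vector, length `ncol(A)`.
#' @export
objective_gradient <- function(spec, weights, im, u, d2 = NULL) {
  dose <- compute_dose(im, u^2)
  ev <- eval_objective(spec, dose, weights, d2 = d2, gradient = TRUE)
  2 * u * as.numeric(Matrix::crossprod(im$A, ev$grad_dose))
}
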