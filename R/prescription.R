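#' Assemble a prescription
#'
#' A prescription bundles the typed constraints driving the objective with
#' the acceptability rules used by plan evaluation. The loop accepts a plan
#' when (i) the PTV coverage reaches its threshold (fraction of the PTV
#' receiving the prescribed minimum dose, default 95%) and (ii) every
#' maximum dose-volume constraint of the prescription holds,
#' `V(D1) <= V1` (non-strict). A separate table of clinical dose-volume
#' `guidelines` can be attached for quality reporting; guidelines are
#' checked with a strict `<` on the volume side but do not gate the loop.
#'
#' @param constraints list of [constraints] records; must contain exactly one
#'   PTV minimum-dose constraint.
#' @param ptv_coverage_pct PTV coverage threshold in percent (default 95).
#' @param evaluation tibble of loop-acceptance dose-volume rules with
#'   columns `structure`, `dose_Gy`, `volume_pct` (a row is satisfied when
#'   `V(dose_Gy) <= volume_pct`); defaults to the prescription's own
#'   `dv_max` constraints.
#' @param guidelines optional tibble of clinical acceptability guidelines,
#'   same columns, checked with strict `<` in reports.
#' @return An object of class `fmo_prescription`.
#' @export
prescription <- function(constraints, ptv_coverage_pct = 95,
                         evaluation = NULL, guidelines = NULL) {
  stopifnot(is.list(constraints),
            all(vapply(constraints, inherits, logical(1), "fmo_constraint")))
  types <- vapply(constraints, `[[`, character(1), "type")
  roles <- vapply(constraints, `[[`, character(1), "role")
  if (sum(types == "min_dose" & roles == "ptv") != 1L) {
    stop("prescription needs exactly one PTV minimum-dose constraint", call. = FALSE)
  }
  if (is.null(evaluation)) {
    dv <- constraints[types == "dv_max"]
    evaluation <- tibble::tibble(
      structure = vapply(dv, `[[`, character(1), "structure"),
      dose_Gy = vapply(dv, `[[`, numeric(1), "d1"),
      volume_pct = vapply(dv, `[[`, numeric(1), "v1")
    )
  }
  stopifnot(all(c("structure", "dose_Gy", "volume_pct") %in% names(evaluation)))
  if (is.null(guidelines)) {
    guidelines <- tibble::tibble(structure = character(), dose_Gy = numeric(),
                                 volume_pct = numeric())
  }
  stopifnot(all(c("structure", "dose_Gy", "volume_pct") %in% names(guidelines)))
  structure(list(constraints = constraints,
                 ptv_coverage_pct = ptv_coverage_pct,
                 evaluation = tibble::as_tibble(evaluation),
                 guidelines = tibble::as_tibble(guidelines)),
            class = "fmo_prescription")
}

#' @export
print.fmo_prescription <- function(x, ...) {
  cat(sprintf("<prescription> %d constraints, PTV coverage >= %g%%, %d evaluation rules\n",
              length(x$constraints), x$ptv_coverage_pct, nrow(x$evaluation)))
  for (con in x$constraints) print(con)
  invisible(x)
}

#' Default LKB parameter sets for the pelvic OARs
#'
#' Literature-tradition defaults (the serial rectum: TD50 76.9 Gy, m 0.13,
#' n 0.09; the more parallel bladder: TD50 80 Gy, m 0.11, n 0.5). These are
#' implementation defaults, exposed here and in the config schema so they
#' can be overridden per run.
#'
#' @return Named list with `rectum` and `bladder` entries, each a list with
#'   `td50`, `m`, `n`.
#' @export
default_lkb_parameters <- function() {
  list(rectum = list(td50 = 76.9, m = 0.13, n = 0.09),
       bladder = list(td50 = 80, m = 0.11, n = 0.5))
}

#' Prostate prescription preset
#'
#' The standard 5-beam prostate prescription the engine ships with: PTV
#' minimum dose 74 Gy and mean dose 78 Gy; maximum dose-volume constraints
#' rectum 50 Gy/40%, 65 Gy/25%, 75 Gy/15% and bladder 65 Gy/35%, 70 Gy/30%,
#' 75 Gy/16%; OAR gEUD prescriptions of 60 Gy (exponent `a = 1/n` of each
#' organ's LKB set); and OAR NTCP prescriptions of 0.05 with the
#' [default_lkb_parameters()]. Loop acceptance: PTV coverage
#' 95% at 74 Gy plus the prescribed dose-volume constraints themselves. The
#' usual clinical dose-volume guideline table (rectum V50 < 50%, V60 < 35%,
#' V65 < 25%, V70 < 20%, V75 < 15%; bladder V65 < 50%, V70 < 35%,
#' V75 < 25%, V80 < 15%) is attached for quality reporting; see
#' [prostate_dv_guidelines()].
#'
#' @param lkb LKB parameter list as from [default_lkb_parameters()].
#' @param geud_pre prescribed OAR gEUD in Gy.
#' @param ntcp_pre prescribed OAR NTCP.
#' @return An `fmo_prescription`.
#' @export
default_prostate_prescription <- function(lkb = default_lkb_parameters(),
                                          geud_pre = 60, ntcp_pre = 0.05) {
  constraints <- list(
    constraint_min_dose("ptv", 74),
    constraint_mean_dose("ptv", 78),
    constraint_dv_max("rectum", 50, 40),
    constraint_dv_max("rectum", 65, 25),
    constraint_dv_max("rectum", 75, 15),
    constraint_dv_max("bladder", 65, 35),
    constraint_dv_max("bladder", 70, 30),
    constraint_dv_max("bladder", 75, 16),
    constraint_geud("rectum", geud_pre, a = 1 / lkb$rectum$n),
    constraint_geud("bladder", geud_pre, a = 1 / lkb$bladder$n),
    constraint_ntcp("rectum", ntcp_pre, lkb$rectum$td50, lkb$rectum$m, lkb$rectum$n),
    constraint_ntcp("bladder", ntcp_pre, lkb$bladder$td50, lkb$bladder$m, lkb$bladder$n)
  )
  prescription(constraints, ptv_coverage_pct = 95,
               guidelines = prostate_dv_guidelines())
}

#' Clinical dose-volume guideline table for the pelvic OARs
#'
#' The standard acceptability guidelines used to judge prostate plan
#' quality: rectum V50 < 50%, V60 < 35%, V65 < 25%, V70 < 20%, V75 < 15%;
#' bladder V65 < 50%, V70 < 35%, V75 < 25%, V80 < 15% (strict inequalities).
#'
#' @return A tibble with columns `structure`, `dose_Gy`, `volume_pct`.
#' @export
prostate_dv_guidelines <- function() {
  tibble::tribble(
    ~structure, ~dose_Gy, ~volume_pct,
    "rectum",  50, 50,
    "rectum",  60, 35,
    "rectum",  65, 25,
    "rectum",  70, 20,
    "rectum",  75, 15,
    "bladder", 65, 50,
    "bladder", 70, 35,
    "bladder", 75, 25,
    "bladder", 80, 15
  )
}

# the PTV minimum-dose constraint of a prescription (drives plan evaluation)
ptv_min_constraint <- function(prescription) {
  for (con in prescription$constraints) {
    if (con$type == "min_dose" && con$role == "ptv") return(con)
  }
  stop("prescription has no PTV minimum-dose constraint", call. = FALSE)
}
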