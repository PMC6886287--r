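structure_dose <- function(dose, mask) {
  m <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(m) == 0) stop("structure mask is empty", call. = FALSE)
  dose[m]
}

#' Cumulative dose-volume histogram
#'
#' `V(d)` is the percentage of structure voxels receiving a dose greater than
#' or equal to `d`. The curve is evaluated exactly on voxels (no dose
#' binning) at the requested dose grid.
#'
#' @param dose voxel dose vector (Gy) over the full grid.
#' @param mask logical mask (or voxel indices) of the structure.
#' @param dose_grid ascending dose values at which to evaluate `V(d)`;
#'   defaults to a 0.25 Gy grid from 0 to just above the structure maximum.
#' @param structure structure name carried into the output.
#' @return A tibble of class `dvh_curve` with columns `structure`, `dose_Gy`,
#'   `volume_pct`.
#' @export
dvh <- function(dose, mask, dose_grid = NULL, structure = "structure") {
  d <- structure_dose(dose, mask)
  if (is.null(dose_grid)) {
    dose_grid <- seq(0, max(d) + 0.25, by = 0.25)
  }
  v <- vapply(dose_grid, function(t) 100 * mean(d >= t), numeric(1))
  out <- tibble::tibble(structure = structure, dose_Gy = dose_grid,
                        volume_pct = v)
  class(out) <- c("dvh_curve", class(out))
  out
}

#' Volume receiving at least a given dose
#'
#' The `V_D` query: percentage of structure voxels with dose >= `d` (closed
#' at the threshold).
#'
#' @inheritParams dvh
#' @param d dose threshold in Gy.
#' @return Percentage in `[0, 100]`.
#' @export
volume_at_dose <- function(dose, mask, d) {
  100 * mean(structure_dose(dose, mask) >= d)
}

#' Minimum dose to the hottest x% of a structure
#'
#' `D_x%` with the descending-rank convention: the dose of rank
#' `ceiling(N * x / 100)` when structure doses are sorted in decreasing
#' order, i.e. the largest dose level `d` with `V(d) >= x`.
#'
#' @inheritParams dvh
#' @param x_pct volume percentage in `(0, 100]`.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dose, mask, x_pct) {
  if (x_pct <= 0 || x_pct > 100) stop("`x_pct` must be in (0, 100]", call. = FALSE)
  d <- sort(structure_dose(dose, mask), decreasing = TRUE)
  d[ceiling(length(d) * x_pct / 100)]
}

#' Conformity index of the reference isodose to the PTV
#'
#' `CI = (Vt_ref / Vt) * (Vt_ref / V_ref)` where `Vt` is the PTV volume,
#' `Vt_ref` the PTV volume at or above the reference dose, and `V_ref` the
#' body volume at or above the reference dose. CI is 1 when the reference
#' isodose coincides exactly with the PTV and decreases with under-coverage
#' or spillage.
#'
#' @param dose voxel dose vector (Gy).
#' @param ptv_mask,body_mask logical masks.
#' @param ref_dose reference (prescription) dose in Gy.
#' @return CI in `[0, 1]`; 0 with a warning when no voxel reaches the
#'   reference dose.
#' @export
conformity_index <- function(dose, ptv_mask, body_mask, ref_dose) {
  if (ref_dose <= 0) stop("`ref_dose` must be positive", call. = FALSE)
  dp <- structure_dose(dose, ptv_mask)
  db <- structure_dose(dose, body_mask)
  vt <- length(dp)
  vt_ref <- sum(dp >= ref_dose)
  v_ref <- sum(db >= ref_dose)
  if (v_ref == 0) {
    warning("no voxel reaches the reference dose; CI set to 0", call. = FALSE)
    return(0)
  }
  (vt_ref / vt) * (vt_ref / v_ref)
}

#' Homogeneity index of the PTV dose
#'
#' `HI = D_5% / D_95%`, the ratio of the minimum dose to the hottest 5% over
#' the minimum dose to the hottest 95% of the PTV; 1 for a perfectly uniform
#' target dose and > 1 otherwise.
#'
#' @param dose voxel dose vector (Gy).
#' @param ptv_mask logical PTV mask with at least 20 voxels.
#' @return HI >= 1.
#' @export
homogeneity_index <- function(dose, ptv_mask) {
  d <- structure_dose(dose, ptv_mask)
  if (length(d) < 20) stop("PTV must have at least 20 voxels for D_5%", call. = FALSE)
  d95 <- dose_at_volume(dose, ptv_mask, 95)
  if (d95 <= 0) stop("D_95% is zero: unirradiated PTV", call. = FALSE)
  dose_at_volume(dose, ptv_mask, 5) / d95
}

#' Generalized equivalent uniform dose (power-mean dose)
#'
#' `gEUD_a = ((1/N) sum_i D_i^a)^(1/a)` (Niemierko). `a = 1` gives the mean
#' dose; large positive `a` approaches the maximum dose (serial organs);
#' negative `a` approaches the minimum (parallel/target use).
#'
#' @param dose voxel dose vector (Gy).
#' @param mask logical mask or voxel indices.
#' @param a power-mean exponent, nonzero.
#' @return gEUD in Gy.
#' @export
geud <- function(dose, mask, a) {
  if (a == 0) stop("`a` must be nonzero", call. = FALSE)
  d <- structure_dose(dose, mask)
  if (any(d < 0)) stop("doses must be nonnegative", call. = FALSE)
  if (a < 0 && any(d == 0)) {
    stop("gEUD with a < 0 is undefined when any voxel dose is zero", call. = FALSE)
  }
  if (a == 1) return(mean(d))
  dmax <- max(d)
  if (dmax == 0) return(0)
  # scale by the max to keep d^a finite for large exponents
  dmax * mean((d / dmax)^a)^(1 / a)
}

#' LKB normal-tissue complication probability
#'
#' Lyman-Kutcher-Burman model via the gEUD reduction:
#' `NTCP = Phi((gEUD_a - TD50) / (m * TD50))` with `a = 1/n`, where `TD50` is
#' the uniform dose giving 50% complication probability, `m` sets the slope,
#' and `n` the volume effect (small `n`: serial organ, gEUD near max dose).
#'
#' @param dose voxel dose vector (Gy).
#' @param mask logical mask or voxel indices.
#' @param td50 TD50 in Gy, positive.
#' @param m slope parameter, positive.
#' @param n volume-effect parameter, positive.
#' @return Complication probability in `(0, 1)`.
#' @export
ntcp_lkb <- function(dose, mask, td50, m, n) {
  if (td50 <= 0 || m <= 0 || n <= 0) {
    stop("LKB parameters td50, m, n must all be positive", call. = FALSE)
  }
  g <- geud(dose, mask, a = 1 / n)
  stats::pnorm((g - td50) / (m * td50))
}

#' Per-structure plan-quality metrics
#'
#' Dose statistics per structure plus CI and HI on the PTV row. Optional
#' gEUD/NTCP columns are filled for structures with radiobiological
#' parameters supplied.
#'
#' @param dose voxel dose vector (Gy).
#' @param phantom a `phantom`.
#' @param ref_dose reference dose for the conformity index (Gy).
#' @param biology optional named list: per structure name, a list with `a`
#'   (gEUD exponent) and optionally `td50`, `m`, `n` for NTCP.
#' @return A tibble, one row per structure: `structure`, `role`, `n_voxels`,
#'   `D_min`, `D_mean`, `D_max`, `D5`, `D95`, `CI`, `HI`, `gEUD`, `NTCP`.
#' @export
plan_metrics <- function(dose, phantom, ref_dose = NULL, biology = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  purrr::map_dfr(names(phantom$masks), function(nm) {
    mask <- phantom$masks[[nm]]
    d <- structure_dose(dose, mask)
    is_ptv <- phantom$roles[[nm]] == "ptv"
    bio <- biology[[nm]]
    tibble::tibble(
      structure = nm, role = phantom$roles[[nm]], n_voxels = length(d),
      D_min = min(d), D_mean = mean(d), D_max = max(d),
      D5 = dose_at_volume(dose, mask, 5),
      D95 = dose_at_volume(dose, mask, 95),
      CI = if (is_ptv && !is.null(ref_dose)) {
        conformity_index(dose, mask, structure_mask(phantom, role = "body"), ref_dose)
      } else NA_real_,
      HI = if (is_ptv && length(d) >= 20) homogeneity_index(dose, mask) else NA_real_,
      gEUD = if (!is.null(bio$a)) geud(dose, mask, bio$a) else NA_real_,
      NTCP = if (!is.null(bio$td50)) ntcp_lkb(dose, mask, bio$td50, bio$m, bio$n) else NA_real_
    )
  })
}
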