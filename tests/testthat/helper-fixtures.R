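# Shared fixtures, built in code at test time.

# Small phantom for fast end-to-end loops: 24x24 grid, one PTV, two OARs,
# same topology as the prostate preset at coarser scale.
tiny_spec <- function() {
  phantom_spec(
    grid_shape = c(24L, 24L),
    voxel_size = 5,
    structures = list(
      list(name = "body", role = "body", shape = "disk", center = c(0, 0), radius = 55),
      list(name = "ptv", role = "ptv", shape = "disk", center = c(0, 0), radius = 14),
      list(name = "rectum", role = "oar", shape = "crescent", center = c(0, -20),
           radius = 11, carve_center = c(0, 0), carve_radius = 15),
      list(name = "bladder", role = "oar", shape = "disk", center = c(0, 28), radius = 13)
    )
  )
}

tiny_problem <- function() {
  ph <- generate_phantom(tiny_spec())
  im <- compute_influence_matrix(ph, beam_spec())
  list(phantom = ph, im = im)
}

# Influence matrix wrapper around an explicit (dense) matrix, for oracle
# tests where A is hand-chosen. Grid bookkeeping is minimal but valid.
manual_im <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  structure(
    list(A = A,
         beamlets = tibble::tibble(beamlet = seq_len(ncol(A)),
                                   angle_deg = 0, offset_mm = seq_len(ncol(A))),
         voxels = tibble::tibble(voxel = seq_len(nrow(A)),
                                 row = seq_len(nrow(A)), col = 1L,
                                 x_mm = 0, y_mm = 0, in_body = TRUE),
         grid_shape = c(nrow(A), 1L),
         kernel = dose_kernel(), beams = beam_spec(gantry_angles_deg = 0)),
    class = "influence_matrix"
  )
}

# Random strictly-positive dose vectors kept away from the kinks of the
# step-gated subscores, so central differences see a smooth function.
away_from <- function(x, thresholds, margin) {
  for (t in thresholds) x[abs(x - t) < margin] <- x[abs(x - t) < margin] + 2 * margin
  x
}

# Finite-difference gradient audit: random single-subscore instances per
# constraint type, kept away from the penalty kinks; returns the worst
# relative error and the number of clean instances per type.
fd_gradient_suite <- function(n_per_type = 20, seed = 23) {
  set.seed(seed)
  n_vox <- 30; n_blt <- 8
  con_builders <- list(
    min_dose = function() constraint_min_dose("s", runif(1, 18, 25)),
    mean_dose = function() constraint_mean_dose("s", runif(1, 15, 25)),
    max_dose = function() constraint_max_dose("s", runif(1, 15, 22)),
    dv_max = function() constraint_dv_max("s", runif(1, 12, 18), runif(1, 20, 40)),
    geud = function() constraint_geud("s", runif(1, 14, 20), a = sample(c(2, 4, 8), 1)),
    ntcp = function() constraint_ntcp("s", 0.05, runif(1, 14, 20), 0.13, 0.25)
  )
  worst <- 0
  n_checked <- integer(0)
  for (type in names(con_builders)) {
    n_checked[type] <- 0L
    for (rep_i in seq_len(n_per_type * 4)) {
      A <- matrix(runif(n_vox * n_blt, 0, 0.3), n_vox, n_blt)
      im <- manual_im(A)
      con <- con_builders[[type]]()
      spec <- structure(
        list(model = "dv",
             subscores = list(list(index = 1L, constraint = con, structure = "s",
                                   role_in_objective = "oar_sparing",
                                   voxels = seq_len(n_vox))),
             n_subscores = 1L),
        class = "objective_spec"
      )
      u <- runif(n_blt, 2.5, 5.5)
      dose <- compute_dose(im, u^2)
      # keep step-gated terms away from their kinks so the central difference
      # sees the same smooth branch as the analytic derivative
      if (type %in% c("min_dose", "max_dose")) {
        thr <- if (type == "min_dose") con$d_min else con$d_max
        if (any(abs(dose - thr) < 0.05)) next
      }
      if (type == "dv_max") {
        d2 <- compute_d2(dose, con$v1)
        # the quantile voxel itself defines d2; only *other* voxels near the
        # window edges make the branch ambiguous under perturbation
        if (any(abs(dose - con$d1) < 0.05)) next
        if (any(abs(dose[dose != d2] - d2) < 0.05)) next
      }
      if (type == "geud" &&
          abs(geud(dose, seq_len(n_vox), con$a) - con$geud_pre) < 0.05) next
      if (type == "ntcp") {
        p <- ntcp_lkb(dose, seq_len(n_vox), con$td50, con$m, con$n)
        if (abs(p - con$ntcp_pre) < 1e-3 || p > 1 - 1e-9) next
      }
      g <- objective_gradient(spec, 1, im, u)
      h <- 1e-4 * pmax(abs(u), 1)
      fd <- vapply(seq_along(u), function(j) {
        up <- u; up[j] <- up[j] + h[j]
        dn <- u; dn[j] <- dn[j] - h[j]
        fp <- autofmo:::eval_objective(spec, compute_dose(im, up^2))$f
        fm <- autofmo:::eval_objective(spec, compute_dose(im, dn^2))$f
        (fp - fm) / (2 * h[j])
      }, numeric(1))
      worst <- max(worst, max(abs(g - fd)) / max(abs(fd), 1e-8))
      n_checked[type] <- n_checked[type] + 1L
      if (n_checked[type] >= n_per_type) break
    }
  }
  list(max_rel_err = worst, n_checked = n_checked)
}
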