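#' Describe a coplanar parallel beam arrangement
#'
#' @param gantry_angles_deg gantry angles in degrees, clockwise from north
#'   (anterior), in `[0, 360)`.
#' @param beamlet_width lateral beamlet spacing in mm.
#' @param field_margin_mm lateral margin added on each side of the PTV
#'   projection when laying out beamlets.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(gantry_angles_deg = c(36, 100, 180, 260, 324),
                      beamlet_width = 5, field_margin_mm = 10) {
  if (length(gantry_angles_deg) == 0) stop("no beam angles given", call. = FALSE)
  if (any(gantry_angles_deg < 0 | gantry_angles_deg >= 360)) {
    stop("gantry angles must lie in [0, 360)", call. = FALSE)
  }
  if (beamlet_width <= 0) stop("`beamlet_width` must be positive", call. = FALSE)
  structure(
    list(gantry_angles_deg = as.numeric(gantry_angles_deg),
         beamlet_width = beamlet_width, field_margin_mm = field_margin_mm,
         geometry = "parallel"),
    class = "beam_spec"
  )
}

#' Simplified analytic dose kernel
#'
#' Exponential attenuation along the central axis with Gaussian lateral
#' penumbra. These are engine defaults chosen so that five beams can
#' conformally cover a prostate-scale PTV; they are not measured beam data.
#'
#' @param mu_attenuation linear attenuation coefficient, per mm.
#' @param sigma_penumbra lateral Gaussian falloff, mm.
#' @param floor_frac influence entries below this fraction of a beamlet's
#'   maximum are dropped to keep the matrix sparse.
#' @return A list of kernel parameters.
#' @export
dose_kernel <- function(mu_attenuation = 0.005, sigma_penumbra = 3,
                        floor_frac = 1e-4) {
  if (mu_attenuation <= 0 || sigma_penumbra <= 0) {
    stop("kernel parameters must be positive", call. = FALSE)
  }
  list(mu_attenuation = mu_attenuation, sigma_penumbra = sigma_penumbra,
       floor_frac = floor_frac)
}

#' Build the beamlet dose-influence matrix
#'
#' For every beamlet a parallel ray bundle is traced through the body: the
#' deposited dose in a voxel is `exp(-mu * depth)` along the beam direction
#' (depth measured from the body entry point of that lateral position) times
#' a Gaussian lateral falloff around the beamlet axis. Voxels outside the
#' body receive no dose. Beamlets are laid out per beam to cover the PTV
#' projection plus `field_margin_mm` on each side.
#'
#' @param phantom a `phantom`.
#' @param beams a [beam_spec()].
#' @param kernel a [dose_kernel()].
#' @return An object of class `influence_matrix`: a list with `A` (sparse
#'   dgCMatrix, n_voxels x n_beamlets, Gy per unit beamlet weight; voxels in
#'   column-major grid order), `beamlets` (tibble: beamlet, angle_deg,
#'   offset_mm), `voxels` (tibble: voxel, row, col, x_mm, y_mm, in_body) and
#'   the generating phantom/beam metadata.
#' @export
compute_influence_matrix <- function(phantom, beams, kernel = dose_kernel()) {
  stopifnot(inherits(phantom, "phantom"), inherits(beams, "beam_spec"))
  nr <- phantom$grid_shape[1]; nc <- phantom$grid_shape[2]
  n_vox <- nr * nc
  xy <- voxel_coords(phantom$grid_shape, phantom$voxel_size)
  body <- structure_mask(phantom, role = "body")
  ptv <- structure_mask(phantom, role = "ptv")
  in_body <- which(body)                     # column-major linear indices
  px <- xy$x[in_body]; py <- xy$y[in_body]
  mu <- kernel$mu_attenuation; sig <- kernel$sigma_penumbra

  rows <- list(); cols <- list(); vals <- list()
  blt_angle <- numeric(0); blt_offset <- numeric(0)
  col0 <- 0L
  for (ang in beams$gantry_angles_deg) {
    th <- ang * pi / 180
    d <- c(-sin(th), -cos(th))               # propagation direction (into patient)
    e <- c(cos(th), -sin(th))                # lateral axis
    s <- px * d[1] + py * d[2]               # depth coordinate along beam
    l <- px * e[1] + py * e[2]               # lateral coordinate

    # body entry depth per lateral bin (bin width = one voxel)
    bin <- as.integer(round(l / phantom$voxel_size))
    entry <- tapply(s, bin, min)
    depth <- s - entry[as.character(bin)]

    # field layout is rotation-invariant: centred on the PTV centroid with
    # half-width = circumscribed PTV radius + margin, so every beam carries
    # the same number of beamlets
    cx <- mean(xy$x[ptv]); cy <- mean(xy$y[ptv])
    r_ptv <- sqrt(max((xy$x[ptv] - cx)^2 + (xy$y[ptv] - cy)^2))
    half <- r_ptv + beams$field_margin_mm
    c0 <- cx * e[1] + cy * e[2]
    n_blt <- max(1L, as.integer(ceiling(2 * half / beams$beamlet_width)))
    offsets <- c0 + (seq_len(n_blt) - (n_blt + 1) / 2) * beams$beamlet_width

    axial <- exp(-mu * depth)
    for (b in seq_len(n_blt)) {
      dose <- axial * exp(-((l - offsets[b])^2) / (2 * sig^2))
      keep <- dose >= kernel$floor_frac * max(dose)
      rows[[length(rows) + 1L]] <- in_body[keep]
      cols[[length(cols) + 1L]] <- rep.int(col0 + b, sum(keep))
      vals[[length(vals) + 1L]] <- dose[keep]
    }
    blt_angle <- c(blt_angle, rep(ang, n_blt))
    blt_offset <- c(blt_offset, offsets)
    col0 <- col0 + n_blt
  }
  A <- Matrix::sparseMatrix(
    i = unlist(rows), j = unlist(cols), x = unlist(vals),
    dims = c(n_vox, col0)
  )
  if (any(Matrix::colSums(A != 0) == 0)) {
    stop("a beamlet column has no nonzero entries", call. = FALSE)
  }
  ptv_cov <- Matrix::rowSums(A[which(ptv), , drop = FALSE] != 0)
  if (any(ptv_cov == 0)) {
    stop("some PTV voxels are covered by no beamlet", call. = FALSE)
  }
  vox_idx <- arrayInd(seq_len(n_vox), c(nr, nc))
  structure(
    list(A = A,
         beamlets = tibble::tibble(beamlet = seq_len(col0),
                                   angle_deg = blt_angle,
                                   offset_mm = blt_offset),
         voxels = tibble::tibble(voxel = seq_len(n_vox),
                                 row = vox_idx[, 1], col = vox_idx[, 2],
                                 x_mm = as.vector(xy$x), y_mm = as.vector(xy$y),
                                 in_body = as.vector(body)),
         grid_shape = phantom$grid_shape,
         kernel = kernel, beams = beams),
    class = "influence_matrix"
  )
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix> %d voxels x %d beamlets (%d beams), %.2f%% nonzero\n",
              nrow(x$A), ncol(x$A), length(unique(x$beamlets$angle_deg)),
              100 * Matrix::nnzero(x$A) / prod(dim(x$A))))
  invisible(x)
}

#' Map beamlet weights to voxel doses
#'
#' The dose model is linear: `dose = A x` with `A` the influence matrix and
#' `x` the nonnegative beamlet weights.
#'
#' @param im an `influence_matrix`.
#' @param x beamlet weight vector, length `ncol(A)`, all entries >= 0.
#' @return Numeric dose vector (Gy) over all grid voxels, column-major.
#' @export
compute_dose <- function(im, x) {
  stopifnot(inherits(im, "influence_matrix"))
  if (length(x) != ncol(im$A)) {
    stop(sprintf("`x` must have length %d", ncol(im$A)), call. = FALSE)
  }
  if (any(x < 0)) stop("beamlet weights must be nonnegative", call. = FALSE)
  as.numeric(im$A %*% x)
}

#' Persist an influence matrix as plain text
#'
#' Writes the sparse entries as a coordinate-triplet CSV (`row`, `col`,
#' `value`) plus a JSON sidecar with the beamlet and voxel index maps.
#'
#' @param im an `influence_matrix`.
#' @param path output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return Invisibly, the two file paths.
#' @export
write_influence_matrix <- function(im, path) {
  stopifnot(inherits(im, "influence_matrix"))
  tr <- Matrix::mat2triplet(im$A)
  readr::write_csv(tibble::tibble(row = tr$i, col = tr$j, value = tr$x), path)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(dims = dim(im$A), grid_shape = im$grid_shape,
         beamlets = im$beamlets,
         voxels = im$voxels[im$voxels$in_body, c("voxel", "row", "col")]),
    sidecar, auto_unbox = FALSE, digits = NA
  )
  invisible(c(path, sidecar))
}
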