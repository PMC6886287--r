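#' Describe a synthetic 2-D planning phantom
#'
#' A phantom specification holds everything needed to rasterize a single-slice
#' planning geometry: the voxel grid, the body contour, and a set of named
#' structures (one PTV, any number of OARs, optionally a normal-tissue ring)
#' built from geometric primitives. Coordinates are in millimetres with the
#' origin at the grid centre, x increasing to the right and y increasing
#' towards "north" (anterior); gantry angles are measured clockwise from
#' north.
#'
#' Supported geometry primitives:
#' \describe{
#'   \item{disk}{`center` (x, y) and `radius`, all mm.}
#'   \item{annulus}{`center`, `inner_radius`, `outer_radius`.}
#'   \item{crescent}{a disk (`center`, `radius`) minus a carving disk
#'     (`carve_center`, `carve_radius`); used for wrap-around OARs such as a
#'     rectum hugging the target.}
#' }
#'
#' @param grid_shape integer pair, grid rows and columns.
#' @param voxel_size voxel side length in mm.
#' @param structures list of structure definitions; each a list with `name`,
#'   `role` (one of `"ptv"`, `"oar"`, `"normal_ring"`, `"body"`), `shape`
#'   (primitive name above) and the primitive's parameters.
#' @param seed integer seed stored with the spec; rasterization is
#'   deterministic, the seed exists so randomized phantom variants derived
#'   from a spec stay reproducible.
#' @param overlap_tol maximum tolerated fraction of PTV voxels that may
#'   overlap an OAR before [generate_phantom()] refuses the spec.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [default_prostate_spec()], [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape, voxel_size, structures, seed = 1L,
                         overlap_tol = 0) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape <= 0L)) {
    stop("`grid_shape` must be two positive integers", call. = FALSE)
  }
  if (!is.numeric(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be positive (mm)", call. = FALSE)
  }
  roles <- vapply(structures, function(s) s$role %||% "", character(1))
  if (sum(roles == "ptv") != 1L) {
    stop("exactly one structure must have role \"ptv\"", call. = FALSE)
  }
  if (sum(roles == "body") != 1L) {
    stop("exactly one structure must have role \"body\"", call. = FALSE)
  }
  names(structures) <- vapply(structures, `[[`, character(1), "name")
  if (anyDuplicated(names(structures))) {
    stop("structure names must be unique", call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         structures = structures, seed = as.integer(seed),
         overlap_tol = overlap_tol),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d grid, %.3g mm voxels, %d structures\n",
              x$grid_shape[1], x$grid_shape[2], x$voxel_size,
              length(x$structures)))
  for (s in x$structures) {
    cat(sprintf("  %-12s %-11s %s\n", s$name, paste0("[", s$role, "]"), s$shape))
  }
  invisible(x)
}

#' Built-in prostate-like phantom preset
#'
#' A 64x64, 2.5 mm single-slice geometry loosely emulating a male pelvis:
#' a circular body contour, a central disk PTV (prostate plus margin), a
#' posterior crescent OAR ("rectum"), an anterior disk OAR ("bladder"), and a
#' normal-tissue ring surrounding the PTV. The preset is a geometric stand-in
#' for patient anatomy, scaled so that a standard 5-beam prostate
#' prescription (74 Gy minimum / 78 Gy mean to the PTV with the usual
#' rectum/bladder dose-volume limits) is achievable.
#'
#' @param ring_width_mm width of the normal-tissue ring around the PTV
#'   (default 15 mm at phantom scale).
#' @param ring_gap_mm gap between the PTV surface and the inner edge of the
#'   ring.
#' @return A `phantom_spec`.
#' @export
default_prostate_spec <- function(ring_width_mm = 15, ring_gap_mm = 5) {
  ptv_r <- 12
  phantom_spec(
    grid_shape = c(64L, 64L),
    voxel_size = 2.5,
    structures = list(
      list(name = "body", role = "body", shape = "disk",
           center = c(0, 0), radius = 75),
      list(name = "ptv", role = "ptv", shape = "disk",
           center = c(0, 0), radius = ptv_r),
      list(name = "rectum", role = "oar", shape = "crescent",
           center = c(0, -20), radius = 11,
           carve_center = c(0, 0), carve_radius = 15),
      list(name = "bladder", role = "oar", shape = "disk",
           center = c(0, 28), radius = 13),
      list(name = "ring", role = "normal_ring", shape = "annulus",
           center = c(0, 0), inner_radius = ptv_r + ring_gap_mm,
           outer_radius = ptv_r + ring_gap_mm + ring_width_mm)
    ),
    seed = 1L
  )
}

# voxel-centre coordinates (mm, origin at grid centre, y up/north)
voxel_coords <- function(grid_shape, voxel_size) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  x <- (seq_len(nc) - (nc + 1) / 2) * voxel_size
  y <- ((nr + 1) / 2 - seq_len(nr)) * voxel_size
  list(x = matrix(rep(x, each = nr), nr, nc),
       y = matrix(rep(y, times = nc), nr, nc))
}

rasterize_structure <- function(s, xy) {
  d2 <- function(center) (xy$x - center[1])^2 + (xy$y - center[2])^2
  switch(s$shape,
    disk = d2(s$center) <= s$radius^2,
    annulus = {
      r2 <- d2(s$center)
      r2 <= s$outer_radius^2 & r2 > s$inner_radius^2
    },
    crescent = d2(s$center) <= s$radius^2 & d2(s$carve_center) > s$carve_radius^2,
    stop(sprintf("unknown geometry primitive \"%s\"", s$shape), call. = FALSE)
  )
}

#' Rasterize a phantom specification onto its voxel grid
#'
#' Turns each geometry primitive into a binary mask over the grid. Masks are
#' clipped to the body contour; the normal-tissue ring additionally excludes
#' the PTV and all OARs. Rasterization is fully deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom`: a list with `grid_shape`,
#'   `voxel_size`, `masks` (named list of logical matrices) and `roles`
#'   (named character vector).
#' @examples
#' ph <- generate_phantom(default_prostate_spec())
#' phantom_structures(ph)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  xy <- voxel_coords(spec$grid_shape, spec$voxel_size)
  masks <- lapply(spec$structures, rasterize_structure, xy = xy)
  roles <- vapply(spec$structures, `[[`, character(1), "role")
  body <- masks[[which(roles == "body")]]
  ptv_name <- names(roles)[roles == "ptv"]
  oar_names <- names(roles)[roles == "oar"]

  for (nm in names(masks)) {
    if (roles[[nm]] != "body") masks[[nm]] <- masks[[nm]] & body
  }
  ptv <- masks[[ptv_name]]
  if (!any(ptv)) stop("PTV mask is empty on this grid", call. = FALSE)
  for (nm in oar_names) {
    overlap <- sum(masks[[nm]] & ptv)
    if (overlap > spec$overlap_tol * sum(ptv)) {
      if (overlap > 0) {
        stop(sprintf("structure \"%s\" overlaps the PTV in %d voxels", nm, overlap),
             call. = FALSE)
      }
    }
  }
  ring_names <- names(roles)[roles == "normal_ring"]
  for (nm in ring_names) {
    excl <- Reduce(`|`, masks[c(ptv_name, oar_names)])
    masks[[nm]] <- masks[[nm]] & !excl
  }
  structure(
    list(grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
         masks = masks, roles = roles, seed = spec$seed),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%d grid, %.3g mm voxels\n",
              x$grid_shape[1], x$grid_shape[2], x$voxel_size))
  print(phantom_structures(x))
  invisible(x)
}

#' Summarize phantom structures as a tibble
#'
#' @param phantom a `phantom`.
#' @return A tibble with one row per structure: name, role, voxel count, and
#'   area in mm^2.
#' @export
phantom_structures <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  tibble::tibble(
    name = names(phantom$masks),
    role = unname(phantom$roles[names(phantom$masks)]),
    n_voxels = vapply(phantom$masks, sum, integer(1), USE.NAMES = FALSE),
    area_mm2 = .data$n_voxels * phantom$voxel_size^2
  )
}

#' Look up a structure mask by name or role
#'
#' @param phantom a `phantom`.
#' @param name structure name; alternatively use `role =` to fetch the unique
#'   structure with that role.
#' @param role structure role (`"ptv"`, `"body"`, ...); ignored when `name`
#'   is given.
#' @return A logical matrix over the grid.
#' @export
structure_mask <- function(phantom, name = NULL, role = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (!is.null(name)) {
    if (!name %in% names(phantom$masks)) {
      stop(sprintf("no structure named \"%s\"", name), call. = FALSE)
    }
    return(phantom$masks[[name]])
  }
  hits <- names(phantom$roles)[phantom$roles == role]
  if (length(hits) != 1L) {
    stop(sprintf("role \"%s\" matches %d structures", role, length(hits)),
         call. = FALSE)
  }
  phantom$masks[[hits]]
}

#' Export structure masks as a voxel-index tibble
#'
#' One row per (structure, voxel) with row/column indices and mm coordinates;
#' suitable for CSV export or plotting with ggplot2.
#'
#' @param phantom a `phantom`.
#' @return A tibble with columns `structure`, `row`, `col`, `x_mm`, `y_mm`.
#' @export
mask_voxels <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  xy <- voxel_coords(phantom$grid_shape, phantom$voxel_size)
  purrr::map_dfr(names(phantom$masks), function(nm) {
    idx <- which(phantom$masks[[nm]], arr.ind = TRUE)
    tibble::tibble(structure = nm, row = idx[, 1], col = idx[, 2],
                   x_mm = xy$x[idx], y_mm = xy$y[idx])
  })
}
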