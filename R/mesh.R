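#' Build a voxel mesh of a disc coupon
#'
#' Discretises a cylindrical immersion-test coupon (diameter x thickness)
#' into identical cubic elements of edge `Le` on a structured grid
#' clipped to the cylinder.  An element belongs to the coupon when its
#' centre lies inside the cylinder; the jagged boundary this produces is
#' accepted, and `Le` is exact by construction (aspect ratio exactly 1).
#' The coupon axis is z with the origin at the centre of the bottom
#' face; all lengths are mm.
#'
#' Exactly one of `target_elements` and `element_size` must be given.
#' With `target_elements`, the edge length is searched around the
#' equal-volume guess `(V / n)^(1/3)` so that the realised element count
#' is as close as possible to the target; voxelising a disc cannot hit
#' an arbitrary count exactly, and the realised count is normally within
#' 15 percent of the target.
#'
#' @param diameter,thickness coupon dimensions in mm, > 0.
#' @param target_elements desired element count (mutually exclusive with
#'   `element_size`).
#' @param element_size cube edge `Le` in mm.
#' @return A `voxel_mesh`: list with `n_elements`, `Le`, `centers`
#'   (n x 3 matrix), `ijk` (grid indices), `adjacency` (n x 6 integer
#'   matrix of face neighbours, 0 where a face is a free surface, slot
#'   order -x, +x, -y, +y, -z, +z), `boundary` (logical), `element_volume`,
#'   `volume`, and the coupon spec.
#' @export
#' @examples
#' mesh <- build_coupon_mesh(15, 3, target_elements = 3600)
#' mesh
build_coupon_mesh <- function(diameter, thickness,
                              target_elements = NULL, element_size = NULL) {
  if (!is.numeric(diameter) || diameter <= 0 ||
      !is.numeric(thickness) || thickness <= 0) {
    stop("coupon diameter and thickness must be positive", call. = FALSE)
  }
  if (is.null(target_elements) == is.null(element_size)) {
    stop("give exactly one of 'target_elements' or 'element_size'",
         call. = FALSE)
  }
  r <- diameter / 2
  vol <- pi * r^2 * thickness
  if (is.null(element_size)) {
    stopifnot(target_elements >= 1)
    guess <- (vol / target_elements)^(1 / 3)
    cand <- guess * seq(0.8, 1.25, by = 0.0025)
    cand <- cand[cand <= thickness]
    counts <- vapply(cand, function(le) disc_grid_count(diameter, thickness, le),
                     numeric(1))
    Le <- cand[which.min(abs(counts - target_elements))]
  } else {
    Le <- as.numeric(element_size)
    if (Le > thickness) {
      stop("element_size exceeds the coupon thickness", call. = FALSE)
    }
  }
  g <- disc_grid(diameter, thickness, Le)
  if (nrow(g$ijk) == 0L) {
    stop("no element centres fall inside the coupon; ",
         "increase the dimensions or refine the mesh", call. = FALSE)
  }
  new_voxel_mesh(g, Le, coupon = list(diameter = diameter, thickness = thickness))
}

#' Build a rectangular bar voxel mesh
#'
#' A small axis-aligned `nx x ny x nz` block of cubic elements, mainly
#' for verification studies (front-speed oracles, hand-traceable
#' inheritance chains) where the disc geometry is in the way.
#'
#' @param nx,ny,nz element counts along x, y, z.
#' @param Le cube edge (mm).
#' @return A `voxel_mesh` (with a `NULL` coupon spec).
#' @export
build_bar_mesh <- function(nx, ny, nz, Le = 1) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, Le > 0)
  ijk <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz)))
  centers <- cbind((ijk[, 1] - 0.5) * Le, (ijk[, 2] - 0.5) * Le,
                   (ijk[, 3] - 0.5) * Le)
  g <- list(ijk = ijk, centers = centers, dims = c(nx, ny, nz))
  new_voxel_mesh(g, Le, coupon = NULL)
}

# centres of a structured grid clipped to the cylinder; the grid is
# registered so one column of cell centres lies on the coupon axis
disc_grid <- function(diameter, thickness, Le) {
  r <- diameter / 2
  m <- ceiling(r / Le)
  nx <- 2L * m + 1L
  nz <- floor(thickness / Le + 0.5)
  if (nz < 1L) {
    return(list(ijk = matrix(0L, 0, 3), centers = matrix(0, 0, 3),
                dims = c(nx, nx, 0L)))
  }
  xs <- (seq_len(nx) - m - 1L) * Le
  ijk <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(nx), k = seq_len(nz)))
  x <- xs[ijk[, 1]]; y <- xs[ijk[, 2]]; z <- (ijk[, 3] - 0.5) * Le
  keep <- (x^2 + y^2) <= r^2
  list(ijk = ijk[keep, , drop = FALSE],
       centers = cbind(x, y, z)[keep, , drop = FALSE],
       dims = c(nx, nx, nz))
}

disc_grid_count <- function(diameter, thickness, Le) {
  nrow(disc_grid(diameter, thickness, Le)$ijk)
}

new_voxel_mesh <- function(g, Le, coupon) {
  ijk <- g$ijk
  dims <- g$dims
  n <- nrow(ijk)
  # linear index of occupied grid cells -> element id
  lin <- array(0L, dim = dims)
  lin[ijk] <- seq_len(n)
  offsets <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L),
                   c(0L, -1L, 0L), c(0L, 1L, 0L),
                   c(0L, 0L, -1L), c(0L, 0L, 1L))
  adjacency <- matrix(0L, n, 6)
  for (s in 1:6) {
    nb <- sweep(ijk, 2, offsets[s, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    idx <- integer(n)
    idx[ok] <- lin[nb[ok, , drop = FALSE]]
    adjacency[, s] <- idx
  }
  structure(
    list(
      n_elements = n,
      Le = Le,
      centers = unname(g$centers),
      ijk = unname(ijk),
      dims = dims,
      adjacency = adjacency,
      boundary = rowSums(adjacency == 0L) > 0L,
      element_volume = Le^3,
      volume = n * Le^3,
      coupon = coupon
    ),
    class = "voxel_mesh"
  )
}

#' @export
print.voxel_mesh <- function(x, ...) {
  cat("<voxel_mesh>\n")
  if (!is.null(x$coupon)) {
    cat(sprintf("  coupon: disc %g mm x %g mm\n",
                x$coupon$diameter, x$coupon$thickness))
  }
  cat(sprintf("  %d cubic elements, Le = %.4g mm, volume = %.4g mm^3\n",
              x$n_elements, x$Le, x$volume))
  cat(sprintf("  %d boundary elements\n", sum(x$boundary)))
  invisible(x)
}

#' Mesh summary table
#'
#' @param mesh a `voxel_mesh`.
#' @return One-row data frame with element count, `Le`, element volume
#'   and total volume, ready for CSV/JSON export.
#' @export
mesh_summary <- function(mesh) {
  stopifnot(inherits(mesh, "voxel_mesh"))
  data.frame(
    n_elements = mesh$n_elements,
    Le_mm = mesh$Le,
    element_volume_mm3 = mesh$element_volume,
    volume_mm3 = mesh$volume,
    diameter_mm = if (is.null(mesh$coupon)) NA_real_ else mesh$coupon$diameter,
    thickness_mm = if (is.null(mesh$coupon)) NA_real_ else mesh$coupon$thickness
  )
}

#' Currently exposed elements
#'
#' An element is exposed when it is not removed and at least one of its
#' six faces is either a free coupon surface or shared with a removed
#' element.  On a fresh state this is exactly the set of
#' boundary-flagged elements.
#'
#' @param mesh a `voxel_mesh`.
#' @param state a `sim_state` sized to `mesh`.
#' @return Integer vector of element indices, increasing.
#' @export
exposed_elements <- function(mesh, state) {
  check_state(mesh, state)
  removed <- state$status == STATUS_REMOVED
  # a zero adjacency slot is a free face; a removed neighbour also exposes
  nb_removed <- matrix(FALSE, mesh$n_elements, 6)
  pos <- mesh$adjacency > 0L
  nb_removed[pos] <- removed[mesh$adjacency[pos]]
  open_face <- mesh$boundary | rowSums(nb_removed) > 0L
  which(open_face & !removed)
}
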