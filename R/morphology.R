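# 3-D morphology on binary masks: connected components (6/26-neighbour),
# border-connected hole filling, and euclidean dilation with per-direction
# millimetre margins. All kernels are compiled; R-level brute-force oracles
# live in the test suite.

#' Label connected components of a mask
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners). 26 is the
#'   package default for lesion masks.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"), connectivity %in% c(6, 26))
  label_components_cpp(mask$values, dim(mask$values), as.integer(connectivity))
}

#' Keep the largest connected component
#'
#' @inheritParams label_components
#' @return a [binary_mask()] containing only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) abort("mask is empty; no component to keep.")
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  new_mask_like(mask, array(lab == keep, dim(mask$values)))
}

#' Fill internal holes of a mask
#'
#' Background voxels not 6-connected to the array border are considered
#' internal holes and are set to TRUE.
#'
#' @inheritParams label_components
#' @return a [binary_mask()] with holes filled.
#' @export
fill_holes <- function(mask) {
  bg <- !mask$values
  lab <- label_components_cpp(bg, dim(bg), 6L)
  d <- dim(bg)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside_labels <- unique(lab[border & bg])
  filled <- mask$values | (bg & !(lab %in% outside_labels))
  new_mask_like(mask, array(filled, d))
}

# Integer voxel offsets for an anisotropic, per-direction euclidean dilation.
# `margins` is a named numeric vector with entries x-, x+, y-, y+, z-, z+ (mm):
# an offset d (voxels) is included when sum((d_mm / m_dir)^2) <= 1, where each
# axis term uses the margin for the sign of that component. A zero margin
# forbids any displacement in that direction.
margin_offsets <- function(margins, spacing) {
  stopifnot(all(c("x-", "x+", "y-", "y+", "z-", "z+") %in% names(margins)),
            all(margins >= 0))
  mx <- ceiling(max(margins[c("x-", "x+")]) / spacing[1])
  my <- ceiling(max(margins[c("y-", "y+")]) / spacing[2])
  mz <- ceiling(max(margins[c("z-", "z+")]) / spacing[3])
  grid <- expand.grid(di = -mx:mx, dj = -my:my, dk = -mz:mz)
  keep <- vapply(seq_len(nrow(grid)), function(r) {
    d <- c(grid$di[r], grid$dj[r], grid$dk[r])
    dmm <- d * spacing
    m <- c(
      margins[[if (d[1] < 0) "x-" else "x+"]],
      margins[[if (d[2] < 0) "y-" else "y+"]],
      margins[[if (d[3] < 0) "z-" else "z+"]]
    )
    total <- 0
    for (ax in 1:3) {
      if (dmm[ax] == 0) next
      if (m[ax] == 0) return(FALSE)
      total <- total + (dmm[ax] / m[ax])^2
    }
    total <= 1 + 1e-9
  }, logical(1))
  as.matrix(grid[keep, , drop = FALSE])
}

#' Expand a mask by millimetre margins
#'
#' Euclidean dilation in millimetres (not voxel counts), with independent
#' margins in each of the six axis directions, supporting the
#' no-expansion-towards-the-bladder rule used in threshold delineation.
#'
#' @param mask a [binary_mask()].
#' @param margin_mm isotropic margin in mm.
#' @param overrides optional named numeric vector overriding individual
#'   directions, e.g. `c("y-" = 0)` for no posterior expansion. Names from
#'   `x-`, `x+`, `y-`, `y+`, `z-`, `z+`.
#' @return the expanded [binary_mask()].
#' @export
expand_mask <- function(mask, margin_mm, overrides = NULL) {
  margins <- stats::setNames(rep(margin_mm, 6),
                             c("x-", "x+", "y-", "y+", "z-", "z+"))
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(margins))
    if (length(bad)) abort(paste0("unknown margin direction: ", bad[1]))
    margins[names(overrides)] <- overrides
  }
  if (all(margins == 0)) return(mask)
  off <- margin_offsets(margins, mask$spacing)
  out <- dilate_offsets_cpp(mask$values, dim(mask$values),
                            matrix(as.integer(off), ncol = 3))
  new_mask_like(mask, out)
}

# Surface voxels: mask voxels with at least one non-mask 6-neighbour
# (array border counts as outside). Returns an n x 3 matrix of world mm
# coordinates of surface voxel centres.
mask_surface_coords <- function(mask) {
  v <- mask$values
  d <- dim(v)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  inside <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_all <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- inside & !nb_all
  idx <- which(surf, arr.ind = TRUE)
  cbind(
    mask$origin[1] + (idx[, 1] - 1) * mask$spacing[1],
    mask$origin[2] + (idx[, 2] - 1) * mask$spacing[2],
    mask$origin[3] + (idx[, 3] - 1) * mask$spacing[3]
  )
}
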