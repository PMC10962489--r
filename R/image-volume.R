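#' @useDynLib petrtac, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% abort .data
#' @importFrom stats sd rnorm rpois runif fft
NULL

#' Value semantics understood by the pipeline
#'
#' Every [image_volume()] carries a declared value semantic which is checked at
#' each operation boundary: `"HU"` (CT Hounsfield units), `"MU_511KEV"` (linear
#' attenuation coefficient at 511 keV, mm^-1), `"ACTIVITY"` (activity
#' concentration, Bq/mL) and `"SUV"` (standardized uptake value, g/mL).
#'
#' @export
SEMANTICS <- c("HU", "MU_511KEV", "ACTIVITY", "SUV")

#' 3-D image volume
#'
#' A 3-D scalar grid with voxel spacing, world origin and a declared value
#' semantic. Voxel `[i, j, k]` (1-based) has world centre
#' `origin + (index - 1) * spacing`; axes are x (right-left), y
#' (posterior-anterior, anterior positive) and z (inferior-superior).
#'
#' @param values numeric 3-D array (finite).
#' @param spacing voxel size `(dx, dy, dz)` in mm, all positive.
#' @param origin world coordinate of the centre of voxel `[1, 1, 1]`, mm.
#' @param semantic one of [SEMANTICS].
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0),
                         semantic = c("HU", "MU_511KEV", "ACTIVITY", "SUV")) {
  semantic <- match.arg(semantic)
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) {
    abort("`values` must be a 3-D array (a 4-D or higher volume is rejected).")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  if (any(!is.finite(values))) abort("`values` must be finite.")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         semantic = semantic),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume [%s]> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$semantic, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Binary mask on an image grid
#'
#' A 3-D logical grid sharing the spacing/origin of a parent [image_volume()].
#' Used for external contours, GTVs and air regions.
#'
#' @param values logical 3-D array.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) abort("`values` must be a 3-D array.")
  storage.mode(values) <- "logical"
  if (anyNA(values)) abort("mask values must be TRUE/FALSE, not NA.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d set (%.3g cm^3)\n",
              d[1], d[2], d[3], sum(x$values), mask_volume(x)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$values)

# ---- internal grid helpers ---------------------------------------------------

assert_semantic <- function(vol, semantic, arg = deparse(substitute(vol))) {
  if (!inherits(vol, "image_volume")) {
    abort(sprintf("`%s` must be an image_volume.", arg))
  }
  if (!vol$semantic %in% semantic) {
    abort(sprintf("`%s` has semantic %s; expected %s.", arg, vol$semantic,
                  paste(semantic, collapse = " or ")))
  }
  invisible(vol)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

assert_same_grid <- function(a, b) {
  if (!same_grid(a, b)) abort("inputs must share the same voxel grid.")
  invisible(TRUE)
}

# World coordinates (mm) of all voxel centres along one axis.
axis_coords <- function(x, axis) {
  n <- dim(x$values)[axis]
  x$origin[axis] + (seq_len(n) - 1) * x$spacing[axis]
}

# Grid centred at the volume mid-point: coordinates relative to grid centre.
centred_axis <- function(x, axis) {
  co <- axis_coords(x, axis)
  co - mean(range(co))
}

new_mask_like <- function(grid, values) {
  binary_mask(values, spacing = grid$spacing, origin = grid$origin)
}

new_volume_like <- function(grid, values, semantic) {
  image_volume(values, spacing = grid$spacing, origin = grid$origin,
               semantic = semantic)
}
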