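# Gross tumour volume delineation: the semi-manual surrogate (fixed SUV
# threshold + explicit edit hook) and the relative 40%-of-SUVmax threshold
# with expansion constraints. The fixed threshold is >=-inclusive; the
# relative threshold is strictly ">" (voxels "above" the threshold).

new_gtv_contour <- function(mask, method, lesion_label, source_image,
                            margin_used = NULL) {
  if (!any(mask$values)) abort("GTV contour is empty.")
  structure(list(mask = mask, method = method, lesion_label = lesion_label,
                 source_image = source_image, margin_used = margin_used),
            class = "gtv_contour")
}

#' @export
print.gtv_contour <- function(x, ...) {
  cat(sprintf("<gtv_contour %s/%s on %s> %.3g cm^3\n", x$lesion_label,
              x$method, x$source_image, mask_volume(x$mask)))
  invisible(x)
}

#' Semi-manual GTV surrogate (fixed SUV threshold)
#'
#' Thresholds the image at a fixed SUV (2.5 g/mL by default, the value
#' considered diagnostic for malignant ano-rectal tumours), keeps the
#' 26-connected component intersecting the seed region, then applies the
#' edit hook (identity by default). The hook is the explicit, logged
#' injection point standing in for the radiologist's manual adjustment.
#'
#' @param suv `SUV` [image_volume()].
#' @param seed_region [binary_mask()] identifying the lesion of interest.
#' @param fixed_threshold SUV threshold in g/mL (inclusive, `>=`).
#' @param edit_hook function `binary_mask -> binary_mask` applied to the
#'   thresholded component.
#' @param lesion_label,source_image labels recorded on the contour.
#' @return a `gtv_contour` with `method = "semi_manual"`.
#' @export
semi_manual_gtv <- function(suv, seed_region, fixed_threshold = 2.5,
                            edit_hook = identity, lesion_label = "primary",
                            source_image = "CTACcba") {
  assert_semantic(suv, "SUV")
  assert_same_grid(suv, seed_region)
  if (fixed_threshold <= 0) abort("`fixed_threshold` must be positive.")
  above <- new_mask_like(suv, suv$values >= fixed_threshold)
  lab <- label_components(above, connectivity = 26)
  hit <- unique(lab[seed_region$values & lab > 0L])
  if (!length(hit)) {
    abort("lesion not FDG-avid at threshold: no voxel >= threshold in the seed region.")
  }
  counts <- vapply(hit, function(h) sum(lab == h & seed_region$values), 0L)
  keep <- hit[which.max(counts)]
  mask <- new_mask_like(suv, array(lab == keep, dim(lab)))
  mask <- edit_hook(mask)
  new_gtv_contour(mask, "semi_manual", lesion_label, source_image)
}

#' Relative-threshold GTV (percentage of SUVmax)
#'
#' Threshold at `fraction` of the maximum SUV inside the manual contour;
#' voxels strictly above the threshold are kept, limited to a millimetre
#' expansion of the manual contour (0.5 cm by default) so that physiological
#' uptake is excluded. Per-direction overrides implement the 0.0 cm
#' expansion towards an abutting bladder.
#'
#' @param suv `SUV` [image_volume()].
#' @param manual a `gtv_contour` (the semi-manual GTV of the same image).
#' @param fraction fraction of SUVmax, default 0.40.
#' @param margin_mm isotropic expansion limit in mm, default 5 (0.5 cm).
#' @param margin_overrides named per-direction overrides in mm, e.g.
#'   `c("y+" = 0)`; see [expand_mask()].
#' @return a `gtv_contour` with `method = "threshold"`.
#' @export
percentage_threshold_gtv <- function(suv, manual, fraction = 0.40,
                                     margin_mm = 5.0, margin_overrides = NULL) {
  assert_semantic(suv, "SUV")
  stopifnot(inherits(manual, "gtv_contour"))
  if (!(fraction > 0 && fraction < 1)) abort("`fraction` must lie in (0, 1).")
  assert_same_grid(suv, manual$mask)
  if (!any(manual$mask$values)) abort("manual contour is empty.")
  thr <- fraction * max(suv$values[manual$mask$values])
  allowed <- expand_mask(manual$mask, margin_mm, margin_overrides)
  mask_vals <- suv$values > thr & allowed$values
  if (!any(mask_vals)) abort("relative threshold produced an empty contour.")
  margins <- stats::setNames(rep(margin_mm, 6),
                             c("x-", "x+", "y-", "y+", "z-", "z+"))
  if (!is.null(margin_overrides)) margins[names(margin_overrides)] <- margin_overrides
  new_gtv_contour(new_mask_like(suv, array(mask_vals, dim(suv$values))),
                  "threshold", manual$lesion_label, manual$source_image,
                  margin_used = margins)
}
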