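# Contour and whole-image comparison: Dice coefficient, symmetric mean
# distance to agreement, volumes, percentage differences (CTACstd - CTACcba
# relative to CTACcba), and per-voxel SUV difference histograms.

#' Volumetric Dice coefficient
#'
#' `2|A n B| / (|A| + |B|)`.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return unitless overlap in `[0, 1]`.
#' @export
dice <- function(a, b) {
  assert_same_grid(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) abort("both masks are empty.")
  2 * sum(a$values & b$values) / (na + nb)
}

#' Mean distance to agreement (symmetric mean surface distance)
#'
#' Surface voxels are mask voxels with at least one non-mask 6-neighbour;
#' the metric is the average of the two directed mean surface distances
#' (voxel centre to nearest voxel centre, in mm), which makes it symmetric
#' in its arguments.
#'
#' @param a,b non-empty [binary_mask()]s on the same grid.
#' @return distance in mm.
#' @export
mean_distance_to_agreement <- function(a, b) {
  assert_same_grid(a, b)
  if (!any(a$values) || !any(b$values)) abort("masks must be non-empty.")
  sa <- mask_surface_coords(a)
  sb <- mask_surface_coords(b)
  d_ab <- mean(nearest_distances_cpp(sa, sb))
  d_ba <- mean(nearest_distances_cpp(sb, sa))
  (d_ab + d_ba) / 2
}

#' Mask volume in cm^3
#'
#' @param mask a [binary_mask()].
#' @return voxel count times voxel volume, in cm^3.
#' @export
mask_volume <- function(mask) {
  sum(mask$values) * prod(mask$spacing) / 1000
}

#' Percentage difference relative to the reference
#'
#' The reporting convention throughout the package:
#' `100 * (x_std - x_cba) / x_cba`, the CTACstd value relative to the
#' CTACcba reference.
#'
#' @param x_std,x_cba scalars (the reference `x_cba` must be non-zero).
#' @return percentage.
#' @export
percent_difference <- function(x_std, x_cba) {
  if (any(x_cba == 0)) abort("reference value is zero.")
  100 * (x_std - x_cba) / x_cba
}

#' Compare two contours
#'
#' @param std,cba `gtv_contour`s (or [binary_mask()]s) delineated on the
#'   CTACstd and CTACcba images.
#' @return a one-row tibble: `dice`, `mda_mm`, `volume_std_cm3`,
#'   `volume_cba_cm3`, `pct_volume_diff`.
#' @export
compare_contours <- function(std, cba) {
  ms <- if (inherits(std, "gtv_contour")) std$mask else std
  mc <- if (inherits(cba, "gtv_contour")) cba$mask else cba
  vs <- mask_volume(ms); vc <- mask_volume(mc)
  if (vs <= 0 || vc <= 0) abort("contours must be non-empty.")
  tibble::tibble(
    dice = dice(ms, mc),
    mda_mm = mean_distance_to_agreement(ms, mc),
    volume_std_cm3 = vs,
    volume_cba_cm3 = vc,
    pct_volume_diff = percent_difference(vs, vc)
  )
}

#' Per-voxel SUV difference histogram for one patient
#'
#' Per-voxel `100 * (std - cba) / cba` inside the external contour, binned
#' into `n_bins` left-closed, right-open bins over `[lo, hi]` (the last bin
#' closed). Values outside the range are discarded, not clamped; voxels with
#' a zero reference value are excluded and counted for QC.
#'
#' @param img_std,img_cba `SUV` [image_volume()]s on the same grid.
#' @param external [binary_mask()] (the 0.05 g/mL contour of the CTACcba
#'   image).
#' @param n_bins,lo,hi histogram specification; defaults 400 bins over
#'   -100 to +100 percent.
#' @return a tibble with one row per bin (`bin_lo`, `bin_mid`, `bin_hi`,
#'   `count`) and attributes `n_discarded`, `n_zero_reference`, `n_inside`.
#' @export
perpixel_histogram <- function(img_std, img_cba, external, n_bins = 400,
                               lo = -100, hi = 100) {
  assert_semantic(img_std, "SUV"); assert_semantic(img_cba, "SUV")
  assert_same_grid(img_std, img_cba)
  assert_same_grid(img_std, external)
  if (!any(external$values)) abort("external contour is empty.")
  std <- img_std$values[external$values]
  cba <- img_cba$values[external$values]
  n_inside <- length(std)
  nz <- cba != 0
  pct <- 100 * (std[nz] - cba[nz]) / cba[nz]
  in_range <- pct >= lo & pct <= hi
  edges <- seq(lo, hi, length.out = n_bins + 1)
  idx <- pmin(findInterval(pct[in_range], edges, left.open = FALSE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble::tibble(
    bin_lo = edges[-(n_bins + 1)],
    bin_hi = edges[-1],
    bin_mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
    count = counts
  )
  attr(out, "n_discarded") <- sum(!in_range)
  attr(out, "n_zero_reference") <- sum(!nz)
  attr(out, "n_inside") <- n_inside
  out
}

#' Cross-patient histogram summary
#'
#' Per-bin mean and standard error (sd / sqrt(n patients)) of the per-patient
#' counts.
#'
#' @param histograms list of per-patient tibbles from [perpixel_histogram()].
#' @return tibble with `bin_lo`, `bin_mid`, `bin_hi`, `mean_count`,
#'   `se_count`.
#' @export
histogram_summary <- function(histograms) {
  stopifnot(length(histograms) >= 1)
  counts <- vapply(histograms, function(h) h$count, numeric(nrow(histograms[[1]])))
  counts <- matrix(counts, ncol = length(histograms))
  n <- length(histograms)
  base <- histograms[[1]][c("bin_lo", "bin_mid", "bin_hi")]
  base$mean_count <- rowMeans(counts)
  base$se_count <- if (n > 1) apply(counts, 1, sd) / sqrt(n) else rep(NA_real_, nrow(counts))
  tibble::as_tibble(base)
}
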