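# Simplified desk-scale PET physics: slice-wise parallel-beam line integrals,
# attenuation of the emission data by the true mu-map, attenuation correction
# by an assumed mu-map, and filtered back-projection. The model deliberately
# replaces the scanner's Bayesian TOF/PSF reconstruction: the claims under
# test concern AC-map content, not reconstruction flavour.

#' Parallel-beam acquisition geometry
#'
#' Angles are uniform over `[0, pi)`; the detector bin width equals the
#' in-plane voxel size and the bins cover the grid diagonal; z is the slice
#' axis.
#'
#' @param n_angles number of projection angles (>= 16).
#' @return object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(n_angles = 180L) {
  n_angles <- as.integer(n_angles)
  if (n_angles < 16L) abort("at least 16 projection angles are required.")
  structure(list(n_angles = n_angles), class = "acquisition_geometry")
}

sino_semantics <- c("LINE_INTEGRAL", "EXPECTED_COUNTS", "COUNTS",
                    "CORRECTED_COUNTS")

new_sinogram <- function(values, geometry, semantic, grid, scale = 1) {
  stopifnot(semantic %in% sino_semantics)
  if (semantic != "LINE_INTEGRAL" && any(values < 0)) {
    abort("count sinograms must be non-negative.")
  }
  structure(list(values = values, geometry = geometry, semantic = semantic,
                 grid = grid[c("spacing", "origin")],
                 shape = dim(grid$values), scale = scale),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sinogram [%s]> %d slices x %d angles x %d bins\n",
              x$semantic, d[1], d[2], d[3]))
  invisible(x)
}

sino_nbins <- function(shape, spacing) {
  diag_mm <- sqrt(sum((shape[1:2] * spacing[1:2])^2))
  nb <- ceiling(diag_mm / spacing[1])
  if (nb %% 2 == 0) nb <- nb + 1L
  as.integer(nb)
}

sino_angles <- function(geom) seq(0, pi, length.out = geom$n_angles + 1)[-(geom$n_angles + 1)]

#' Forward projection (parallel-beam line integrals)
#'
#' Computes, slice by slice, the line integral of the volume along every line
#' of response (units: value * mm).
#'
#' @param vol an [image_volume()].
#' @param geom an [acquisition_geometry()].
#' @return a `sinogram` with semantic `LINE_INTEGRAL` and dimensions
#'   slice x angle x bin.
#' @export
forward_project <- function(vol, geom = acquisition_geometry()) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$values)
  nbins <- sino_nbins(d, vol$spacing)
  angles <- sino_angles(geom)
  step <- min(vol$spacing[1:2]) / 2
  out <- array(0, c(d[3], geom$n_angles, nbins))
  for (k in seq_len(d[3])) {
    out[k, , ] <- radon_slice_cpp(vol$values[, , k, drop = TRUE],
                                  vol$spacing[1], vol$spacing[2],
                                  angles, nbins, vol$spacing[1], step)
  }
  new_sinogram(out, geom, "LINE_INTEGRAL", vol)
}

#' Reconstruction parameters
#'
#' @param filter `"ramp"` (default, minimal-artifact quantitation baseline)
#'   or `"hann"`.
#' @param counts_scale expected total counts per study; `Inf` = noise-free.
#' @param seed integer seed for the Poisson draw.
#' @return object of class `recon_params`.
#' @export
recon_params <- function(filter = c("ramp", "hann"), counts_scale = Inf,
                         seed = 1L) {
  filter <- match.arg(filter)
  if (!(is.infinite(counts_scale) || counts_scale > 0)) {
    abort("`counts_scale` must be positive or Inf.")
  }
  structure(list(filter = filter, counts_scale = counts_scale,
                 seed = as.integer(seed)),
            class = "recon_params")
}

#' Simulate attenuated emission data
#'
#' Expected counts are the activity line integrals attenuated by the TRUE
#' mu-map: `P(activity) * exp(-P(mu_true))`. With finite `counts_scale` the
#' sinogram is scaled to that expected total and Poisson noise is drawn with
#' the given seed; the scale factor is carried so that reconstruction
#' recovers activity units.
#'
#' @param activity `ACTIVITY` [image_volume()] (non-negative).
#' @param mu_true `MU_511KEV` [image_volume()] on the same grid.
#' @param geom an [acquisition_geometry()].
#' @param params a [recon_params()].
#' @return a `sinogram` with semantic `COUNTS`.
#' @export
simulate_emission <- function(activity, mu_true, geom = acquisition_geometry(),
                              params = recon_params()) {
  assert_semantic(activity, "ACTIVITY")
  assert_semantic(mu_true, "MU_511KEV")
  assert_same_grid(activity, mu_true)
  if (any(activity$values < 0)) abort("activity must be non-negative.")
  p_act <- forward_project(activity, geom)
  p_mu <- forward_project(mu_true, geom)
  expected <- p_act$values * exp(-p_mu$values)
  if (is.infinite(params$counts_scale)) {
    return(new_sinogram(expected, geom, "COUNTS", activity, scale = 1))
  }
  tot <- sum(expected)
  if (tot <= 0) abort("expected counts are identically zero.")
  scale <- params$counts_scale / tot
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  counts <- array(rpois(length(expected), expected * scale), dim(expected))
  new_sinogram(counts, geom, "COUNTS", activity, scale = scale)
}

#' Apply attenuation correction factors
#'
#' Multiplies the measured counts entrywise by
#' `ACF = exp(+P(mu_ac))`, the attenuation correction factor of the ASSUMED
#' mu-map. With `mu_ac` equal to the true map this exactly cancels the
#' simulated attenuation.
#'
#' @param sino a `COUNTS` sinogram from [simulate_emission()].
#' @param mu_ac `MU_511KEV` [image_volume()] on the acquisition grid.
#' @param geom the acquisition geometry used for `sino`.
#' @return a `CORRECTED_COUNTS` sinogram.
#' @export
attenuation_correct <- function(sino, mu_ac, geom = sino$geometry) {
  if (!inherits(sino, "sinogram") || sino$semantic != "COUNTS") {
    abort("`sino` must be a COUNTS sinogram.")
  }
  assert_semantic(mu_ac, "MU_511KEV")
  if (!identical(dim(mu_ac$values), sino$shape)) {
    abort("mu-map grid does not match the acquisition grid.")
  }
  acf <- exp(forward_project(mu_ac, geom)$values)
  new_sinogram(sino$values * acf, geom, "CORRECTED_COUNTS",
               list(values = array(0, sino$shape), spacing = sino$grid$spacing,
                    origin = sino$grid$origin),
               scale = sino$scale)
}

ramp_filter_sino <- function(mat, bin_width, filter) {
  nb <- ncol(mat)
  npad <- 2^ceiling(log2(2 * nb))
  freqs <- c(seq(0, npad / 2), seq(npad / 2 - 1, 1)) / (npad * bin_width)
  h <- freqs
  if (filter == "hann") {
    fny <- 1 / (2 * bin_width)
    h <- h * (0.5 + 0.5 * cos(pi * freqs / fny))
    h[freqs > fny] <- 0
  }
  out <- matrix(0, nrow(mat), nb)
  for (a in seq_len(nrow(mat))) {
    p <- c(mat[a, ], rep(0, npad - nb))
    q <- Re(fft(fft(p) * h, inverse = TRUE)) / npad
    out[a, ] <- q[seq_len(nb)]
  }
  out
}

#' Filtered back-projection reconstruction
#'
#' Slice-wise ramp-filtered (optionally Hann-apodised) back-projection onto
#' the original grid. Negative values are clipped to zero, as required by the
#' downstream SUV semantics; the Poisson count scale recorded by
#' [simulate_emission()] is divided out so the result is in activity units.
#'
#' @param sino a `CORRECTED_COUNTS` (or `COUNTS`/`LINE_INTEGRAL`) sinogram.
#' @param geom the acquisition geometry.
#' @param params a [recon_params()] (selects the filter).
#' @return an `ACTIVITY` [image_volume()].
#' @export
reconstruct <- function(sino, geom = sino$geometry, params = recon_params()) {
  stopifnot(inherits(sino, "sinogram"))
  if (geom$n_angles < 16L) abort("insufficient angular coverage.")
  d <- dim(sino$values)
  shape <- sino$shape
  angles <- sino_angles(geom)
  out <- array(0, shape)
  for (k in seq_len(d[1])) {
    filtered <- ramp_filter_sino(sino$values[k, , , drop = TRUE],
                                 sino$grid$spacing[1], params$filter)
    out[, , k] <- backproject_slice_cpp(filtered, sino$grid$spacing[1],
                                        sino$grid$spacing[2], angles,
                                        sino$grid$spacing[1],
                                        shape[1], shape[2])
  }
  out <- out / sino$scale
  out[out < 0] <- 0
  image_volume(out, sino$grid$spacing, sino$grid$origin, "ACTIVITY")
}

#' Convert HU to 511 keV attenuation coefficients
#'
#' Piecewise-linear ("bilinear") conversion:
#' `mu = mu_water * (1 + HU/1000)` for HU <= 0 (clamped at 0), and
#' `mu = mu_water + bone_slope * HU` for HU > 0, with
#' `mu_water = 0.0096` mm^-1 at 511 keV.
#'
#' @param ct an `HU` [image_volume()].
#' @param mu_water water attenuation at 511 keV, mm^-1.
#' @param bone_slope slope above 0 HU, mm^-1 per HU.
#' @return a `MU_511KEV` [image_volume()].
#' @export
hu_to_mu <- function(ct, mu_water = 0.0096, bone_slope = 0.0000525) {
  assert_semantic(ct, "HU")
  hu <- ct$values
  mu <- ifelse(hu <= 0, pmax(mu_water * (1 + hu / 1000), 0),
               mu_water + bone_slope * hu)
  new_volume_like(ct, array(mu, dim(hu)), "MU_511KEV")
}

#' Convert activity concentration to SUV
#'
#' Body-weight SUV: `SUV = C / (A / (W * 1000))` with C the activity
#' concentration (Bq/mL), A the injected activity decay-corrected to the
#' scan start (Bq) and W the body weight (kg; W*1000 g approximates the
#' distribution volume in mL). Units g/mL.
#'
#' @param act an `ACTIVITY` [image_volume()].
#' @param meta a [patient_meta()].
#' @return an `SUV` [image_volume()].
#' @export
to_suv <- function(act, meta) {
  assert_semantic(act, "ACTIVITY")
  stopifnot(inherits(meta, "patient_meta"))
  denom <- decayed_activity_bq(meta) / (meta$weight_kg * 1000)
  if (denom <= 0) abort("invalid injected activity or weight.")
  new_volume_like(act, act$values / denom, "SUV")
}
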