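# Construction of the two hardware AC-map variants: CTACstd (patient +
# scanner bed only) and CTACcba (patient + couch + coil bridge + anterior
# coil), from a CT volume, an MR-derived external contour and hardware
# models. Every voxel-modifying step appends a provenance record.

#' Rigid transform
#'
#' @param rotation_deg rotations about the x, y, z axes, degrees, applied in
#'   that order about the grid centre.
#' @param translation_mm translation in mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0)) {
  stopifnot(length(rotation_deg) == 3, length(translation_mm) == 3)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm)),
            class = "rigid_transform")
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3)
  ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3)
  rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

#' Resample a CT onto a reference grid under a rigid transform
#'
#' Trilinear resampling; voxels mapping outside the source field of view are
#' set to -1000 HU (air). In synthetic mode the transform is the identity.
#'
#' @param ct `HU` [image_volume()].
#' @param transform a [rigid_transform()] mapping reference coordinates into
#'   CT coordinates (about the grid centre).
#' @param reference an [image_volume()] or [binary_mask()] defining the
#'   target grid.
#' @return `HU` [image_volume()] on the reference grid.
#' @export
resample_ct_to_reference <- function(ct, transform = rigid_transform(),
                                     reference = ct) {
  assert_semantic(ct, "HU")
  d_ref <- dim(reference$values)
  co <- grid_coords(d_ref, reference$spacing, reference$origin)
  ctr_ref <- vapply(1:3, function(a) mean(range(co[[a]])), 0)
  pts <- as.matrix(expand.grid(x = co$x, y = co$y, z = co$z))
  rel <- sweep(pts, 2, ctr_ref)
  rot <- rotation_matrix(transform$rotation_deg)
  src <- rel %*% t(rot)
  src <- sweep(src, 2, transform$translation_mm, `+`)
  d_src <- dim(ct$values)
  co_src <- grid_coords(d_src, ct$spacing, ct$origin)
  ctr_src <- vapply(1:3, function(a) mean(range(co_src[[a]])), 0)
  src <- sweep(src, 2, ctr_src, `+`)
  idx <- sweep(sweep(src, 2, ct$origin), 2, ct$spacing, `/`)
  vals <- trilinear_sample_cpp(ct$values, d_src, idx, fill = -1000)
  if (all(vals == -1000)) abort("grids do not overlap after the transform.")
  image_volume(array(vals, d_ref), reference$spacing, reference$origin, "HU")
}

#' Harmonize CT and MR external contours
#'
#' Crops the registered CT to the MR external contour and sets any tissue
#' inside the MR contour but outside the CT contour to water density (0 HU).
#'
#' @param ct `HU` [image_volume()].
#' @param ct_external,mr_external [binary_mask()]s on the CT grid.
#' @return harmonized `HU` [image_volume()] with attribute `n_waterfilled`.
#' @export
harmonize_externals <- function(ct, ct_external, mr_external) {
  assert_semantic(ct, "HU")
  assert_same_grid(ct, ct_external)
  assert_same_grid(ct, mr_external)
  if (!any(mr_external$values)) abort("MR external contour is empty.")
  hu <- ct$values
  hu[!mr_external$values] <- -1000
  waterfill <- mr_external$values & !ct_external$values
  hu[waterfill] <- 0
  out <- new_volume_like(ct, hu, "HU")
  attr(out, "n_waterfilled") <- sum(waterfill)
  out
}

#' Fill internal air with water density
#'
#' Voxels inside the external contour with HU below the air threshold are set
#' to 0 HU (water), emulating the automatic delineation and water-fill of
#' bowel gas. Idempotent.
#'
#' @param ct `HU` [image_volume()].
#' @param external [binary_mask()] of the patient outline.
#' @param air_hu_threshold HU below which a voxel counts as air; default
#'   -400 separates gas from soft tissue on a water-equivalent phantom.
#' @return `HU` [image_volume()] with attribute `n_airfilled` (count of
#'   modified voxels).
#' @export
fill_internal_air <- function(ct, external, air_hu_threshold = -400) {
  assert_semantic(ct, "HU")
  assert_same_grid(ct, external)
  if (!any(external$values)) abort("external contour is empty.")
  hu <- ct$values
  sel <- external$values & hu < air_hu_threshold
  hu[sel] <- 0
  out <- new_volume_like(ct, hu, "HU")
  attr(out, "n_airfilled") <- sum(sel)
  out
}

#' Position hardware models relative to the patient
#'
#' The couch slab abuts the posterior extremum of the body mask; the
#' bridge/coil shells are shifted laterally/vertically by the measured
#' offsets and centred in z at the coil-bridge landmark, displaced by the
#' scanner table position relative to the landmarked reference
#' (`z_centre = grid z-centre + (table_z - landmark_z)`).
#'
#' @param models list of [hardware_model()].
#' @param body [binary_mask()] of the patient.
#' @param lateral_offset_mm,vertical_offset_mm measured shell offsets, mm.
#' @param table_z_mm scanner table position during the PET acquisition, mm.
#' @param landmark_z_mm table position at which the coil bridge is centred on
#'   the grid, mm.
#' @return named list of positioned `MU_511KEV` overlays with a
#'   `provenance` attribute recording each placement.
#' @export
place_hardware <- function(models, body, lateral_offset_mm = 0,
                           vertical_offset_mm = 0, table_z_mm = 0,
                           landmark_z_mm = 0) {
  stopifnot(all(is.finite(c(lateral_offset_mm, vertical_offset_mm,
                            table_z_mm, landmark_z_mm))))
  z_shift <- table_z_mm - landmark_z_mm
  placed <- lapply(models, function(m) {
    if (m$kind %in% c("bridge_shell", "anterior_coil_shell")) {
      m$placement <- m$placement +
        c(lateral_offset_mm, vertical_offset_mm, z_shift)
    }
    m
  })
  overlays <- build_hardware(placed, grid = body, body = body)
  attr(overlays, "provenance") <- lapply(placed, function(m) {
    list(step = "place_hardware", kind = m$kind, placement = m$placement,
         mu = m$mu)
  })
  overlays
}

#' Compose an AC-map variant
#'
#' `CTACstd` is the patient mu-map plus the scanner bed; `CTACcba` adds the
#' radiotherapy hardware overlays. Overlapping hardware/bed voxels take the
#' voxelwise maximum (the physical mu of the occupying material), never the
#' sum.
#'
#' @param patient_mu `MU_511KEV` [image_volume()] of the patient.
#' @param overlays named list of hardware overlays from [place_hardware()].
#' @param include_hardware logical; `FALSE` yields `CTACstd`, `TRUE`
#'   `CTACcba`.
#' @param scanner_bed_mu optional `MU_511KEV` overlay of the scanner bed,
#'   included in both variants.
#' @return object of class `ac_map_variant` with fields `label`, `mu` and
#'   `provenance`.
#' @export
compose_ac_map <- function(patient_mu, overlays, include_hardware,
                           scanner_bed_mu = NULL) {
  assert_semantic(patient_mu, "MU_511KEV")
  mu <- patient_mu$values
  prov <- list(list(step = "patient_mu"))
  if (!is.null(scanner_bed_mu)) {
    assert_semantic(scanner_bed_mu, "MU_511KEV")
    assert_same_grid(patient_mu, scanner_bed_mu)
    mu <- pmax(mu, scanner_bed_mu$values)
    prov <- c(prov, list(list(step = "scanner_bed", max_mu = max(scanner_bed_mu$values))))
  }
  label <- "CTACstd"
  if (isTRUE(include_hardware)) {
    label <- "CTACcba"
    for (nm in names(overlays)) {
      if (nm == "scanner_bed") next
      ov <- overlays[[nm]]
      assert_same_grid(patient_mu, ov)
      mu <- pmax(mu, ov$values)
      prov <- c(prov, list(list(step = "hardware", kind = nm,
                                max_mu = max(ov$values))))
    }
  }
  structure(list(label = label,
                 mu = new_volume_like(patient_mu, mu, "MU_511KEV"),
                 provenance = prov),
            class = "ac_map_variant")
}

#' @export
print.ac_map_variant <- function(x, ...) {
  cat(sprintf("<ac_map_variant %s> %d provenance steps\n",
              x$label, length(x$provenance)))
  invisible(x)
}
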