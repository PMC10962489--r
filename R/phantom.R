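# Synthetic digital-pelvis phantoms: a water-equivalent body ellipse with
# internal air pockets and FDG-avid lesions, plus parametric radiotherapy
# hardware (flat couch slab, coil-bridge shell, anterior-coil shell).

#' Injection metadata for SUV conversion
#'
#' @param activity_mbq injected activity in MBq (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @param uptake_min injection-to-scan interval in minutes (>= 0).
#' @param half_life_min radionuclide half-life in minutes; default 109.77
#'   (18F).
#' @param glucose_mmol_l optional blood glucose, informational only.
#' @return object of class `patient_meta`.
#' @export
patient_meta <- function(activity_mbq = 245, weight_kg = 70, uptake_min = 70,
                         half_life_min = 109.77, glucose_mmol_l = NULL) {
  stopifnot(activity_mbq > 0, weight_kg > 0, uptake_min >= 0, half_life_min > 0)
  structure(list(activity_mbq = activity_mbq, weight_kg = weight_kg,
                 uptake_min = uptake_min, half_life_min = half_life_min,
                 glucose_mmol_l = glucose_mmol_l),
            class = "patient_meta")
}

# Injected activity decay-corrected to scan start, in Bq.
decayed_activity_bq <- function(meta) {
  meta$activity_mbq * 1e6 * 2^(-meta$uptake_min / meta$half_life_min)
}

#' Specify one lesion
#'
#' @param centre lesion centre (x, y, z) in mm, world coordinates.
#' @param radii ellipsoid semi-axes in mm (scalar recycled to 3).
#' @param peak_suv peak SUV in g/mL (must exceed the background SUV).
#' @param profile `"uniform"` (flat at `peak_suv` inside the ellipsoid) or
#'   `"gaussian"` (gaussian falloff with sigma = radius / 2, evaluated inside
#'   the ellipsoid support).
#' @param label `"primary"` or `"nodal"`.
#' @param abuts_bladder `NULL`, or a direction string (`"x-"`, `"x+"`, `"y-"`,
#'   `"y+"`, `"z-"`, `"z+"`) towards which threshold delineation must not
#'   expand.
#' @return object of class `tumour_spec`.
#' @export
tumour_spec <- function(centre, radii, peak_suv,
                        profile = c("gaussian", "uniform"),
                        label = c("primary", "nodal"),
                        abuts_bladder = NULL) {
  profile <- match.arg(profile)
  label <- match.arg(label)
  radii <- rep_len(as.numeric(radii), 3)
  stopifnot(length(centre) == 3, all(radii > 0), peak_suv > 0)
  if (!is.null(abuts_bladder) &&
      !abuts_bladder %in% c("x-", "x+", "y-", "y+", "z-", "z+")) {
    abort("`abuts_bladder` must be one of x-/x+/y-/y+/z-/z+.")
  }
  structure(list(centre = as.numeric(centre), radii = radii,
                 peak_suv = peak_suv, profile = profile, label = label,
                 abuts_bladder = abuts_bladder),
            class = "tumour_spec")
}

#' Specify a digital pelvis phantom
#'
#' The body is an elliptic cylinder of water-equivalent tissue (0 HU) in air
#' (-1000 HU); air pockets (bowel gas) are -1000 HU ellipsoids inside the
#' body; lesions are SUV ellipsoids added on a uniform background uptake.
#'
#' @param shape grid dimensions (nx, ny, nz).
#' @param spacing voxel size (dx, dy, dz) in mm.
#' @param body_semiaxes in-plane body ellipse semi-axes (ax, ay) in mm.
#' @param background_suv uniform background SUV inside the body, g/mL (> 0).
#' @param tumours list of [tumour_spec()].
#' @param air_pockets list of `list(centre = c(x,y,z), radii = c(rx,ry,rz))`.
#' @param jitter_mm standard deviation of the seeded lesion-placement jitter
#'   applied to tumour centres (0 disables).
#' @param seed integer seed controlling jitter.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 8), spacing = c(2.5, 2.5, 3),
                         body_semiaxes = c(85, 65), background_suv = 1.5,
                         tumours = list(), air_pockets = list(),
                         jitter_mm = 0, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape[1:2] >= 4), shape[3] >= 1, length(spacing) == 3,
            all(spacing > 0), length(body_semiaxes) == 2,
            all(body_semiaxes > 0), background_suv > 0, jitter_mm >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 body_semiaxes = as.numeric(body_semiaxes),
                 background_suv = background_suv, tumours = tumours,
                 air_pockets = air_pockets, jitter_mm = jitter_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Grid centred on the volume: origin so that world (0,0,0) is the grid centre.
centred_origin <- function(shape, spacing) -(shape - 1) / 2 * spacing

# Normalised ellipsoid radius^2 field for a centre/radii on a grid.
ellipsoid_r2 <- function(coords, centre, radii) {
  xs <- (coords$x - centre[1]) / radii[1]
  ys <- (coords$y - centre[2]) / radii[2]
  zs <- (coords$z - centre[3]) / radii[3]
  outer3 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  outer3
}

grid_coords <- function(shape, spacing, origin) {
  list(x = origin[1] + (seq_len(shape[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(shape[3]) - 1) * spacing[3])
}

#' Build a synthetic phantom
#'
#' Generates the CT-like attenuation volume, the ground-truth activity volume
#' and the body/lesion masks for one synthetic patient. Deterministic given
#' the specification's seed.
#'
#' @param spec a [phantom_spec()].
#' @param meta a [patient_meta()]; used to convert the SUV specification into
#'   an activity concentration (Bq/mL) consistent with [to_suv()].
#' @return list with elements `ct` (HU [image_volume()]), `activity`
#'   (Bq/mL volume), `body` ([binary_mask()]), `tumour_masks` (list of
#'   [binary_mask()], one per lesion, named by label and index), `tumours`
#'   (the jittered specs actually used) and `meta`.
#' @export
build_phantom <- function(spec, meta = patient_meta()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(meta, "patient_meta"))
  origin <- centred_origin(spec$shape, spec$spacing)
  co <- grid_coords(spec$shape, spec$spacing, origin)

  body2d <- outer((co$x / spec$body_semiaxes[1])^2,
                  (co$y / spec$body_semiaxes[2])^2, `+`) <= 1
  body <- array(body2d, spec$shape)

  # Seeded placement jitter; geometry otherwise deterministic.
  tumours <- spec$tumours
  if (length(tumours) && spec$jitter_mm > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    tumours <- lapply(tumours, function(tu) {
      # clamp at 2 sigma so placement stays valid for every seed
      j <- pmin(pmax(rnorm(3, 0, spec$jitter_mm), -2 * spec$jitter_mm),
                2 * spec$jitter_mm)
      tu$centre <- tu$centre + j
      tu
    })
  }

  ct <- array(-1000, spec$shape)
  ct[body] <- 0
  suv <- array(0, spec$shape)
  suv[body] <- spec$background_suv

  for (ap in spec$air_pockets) {
    radii <- rep_len(as.numeric(ap$radii), 3)
    inside <- ellipsoid_r2(co, ap$centre, radii) <= 1
    if (any(inside & !body)) abort("air pocket extends outside the body.")
    ct[inside] <- -1000
    suv[inside] <- 0
  }

  tumour_masks <- list()
  for (i in seq_along(tumours)) {
    tu <- tumours[[i]]
    if (tu$peak_suv <= spec$background_suv) {
      abort("tumour peak SUV must exceed the background SUV.")
    }
    r2 <- ellipsoid_r2(co, tu$centre, tu$radii)
    inside <- r2 <= 1
    if (!any(inside)) abort("tumour has no voxel support on this grid.")
    if (any(inside & !body)) {
      abort(sprintf("tumour %d extends outside the body ellipse.", i))
    }
    if (tu$profile == "uniform") {
      suv[inside] <- tu$peak_suv
    } else {
      # gaussian falloff with sigma = radius/2: value = bg + amp * exp(-2 r_n^2)
      amp <- tu$peak_suv - spec$background_suv
      suv[inside] <- spec$background_suv + amp * exp(-2 * r2[inside])
    }
    tumour_masks[[paste0(tu$label, "_", i)]] <-
      binary_mask(inside, spec$spacing, origin)
  }

  act_per_suv <- decayed_activity_bq(meta) / (meta$weight_kg * 1000)
  list(
    ct = image_volume(ct, spec$spacing, origin, "HU"),
    activity = image_volume(suv * act_per_suv, spec$spacing, origin, "ACTIVITY"),
    body = binary_mask(body, spec$spacing, origin),
    tumour_masks = tumour_masks,
    tumours = tumours,
    meta = meta
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- hardware ---------------------------------------------------------------

#' Parametric radiotherapy hardware
#'
#' @param kind `"couch_slab"` (flat slab abutting the posterior body surface),
#'   `"bridge_shell"` or `"anterior_coil_shell"` (upper-half annular arcs
#'   above the pelvis), or `"scanner_bed"` (thin slab below the couch,
#'   present in both AC-map variants).
#' @param thickness_mm radial/vertical thickness (> 0).
#' @param mu linear attenuation coefficient at 511 keV, mm^-1 (>= 0).
#' @param lateral_extent_mm full lateral width for slabs.
#' @param z_extent_mm full extent along z (default: whole grid).
#' @param arc_radius_mm inner radius of shell arcs, mm.
#' @param placement numeric `(lateral_offset, vertical_offset, z_centre)` in
#'   mm relative to the grid centre.
#' @return object of class `hardware_model`.
#' @export
hardware_model <- function(kind = c("couch_slab", "bridge_shell",
                                    "anterior_coil_shell", "scanner_bed"),
                           thickness_mm, mu, lateral_extent_mm = Inf,
                           z_extent_mm = Inf, arc_radius_mm = NULL,
                           placement = c(0, 0, 0)) {
  kind <- match.arg(kind)
  stopifnot(thickness_mm > 0, mu >= 0, length(placement) == 3)
  if (kind %in% c("bridge_shell", "anterior_coil_shell") &&
      is.null(arc_radius_mm)) {
    abort("shell hardware requires `arc_radius_mm`.")
  }
  structure(list(kind = kind, thickness_mm = thickness_mm, mu = mu,
                 lateral_extent_mm = lateral_extent_mm,
                 z_extent_mm = z_extent_mm, arc_radius_mm = arc_radius_mm,
                 placement = as.numeric(placement)),
            class = "hardware_model")
}

#' Default hardware set
#'
#' Couch slab, coil-bridge shell and anterior-coil shell with attenuation
#' values chosen so that the simulated whole-image SUV loss from omitting
#' them falls in the high-single-digit to high-teens percent range reported
#' for real radiotherapy hardware. The values are configuration, not claims
#' about any specific device.
#'
#' @param couch_mu,bridge_mu,coil_mu linear attenuation coefficients mm^-1.
#' @param bridge_radius_mm,coil_radius_mm inner arc radii, mm.
#' @return list of [hardware_model()].
#' @export
default_hardware <- function(couch_mu = 0.0032, bridge_mu = 0.0024,
                             coil_mu = 0.0032, bridge_radius_mm = 98,
                             coil_radius_mm = 88) {
  list(
    hardware_model("couch_slab", thickness_mm = 20, mu = couch_mu),
    hardware_model("bridge_shell", thickness_mm = 8, mu = bridge_mu,
                   arc_radius_mm = bridge_radius_mm),
    hardware_model("anterior_coil_shell", thickness_mm = 10, mu = coil_mu,
                   arc_radius_mm = coil_radius_mm)
  )
}

# Rasterize one hardware model onto a grid as a MU_511KEV overlay.
# `posterior_mm` is the world y of the most posterior body voxel centre
# (needed for couch_slab and scanner_bed).
rasterize_hardware <- function(model, grid, body = NULL, posterior_mm = NULL,
                               couch_thickness_mm = NULL) {
  shape <- dim(grid$values)
  co <- grid_coords(shape, grid$spacing, grid$origin)
  mu <- array(0, shape)
  pl <- model$placement
  zc <- mean(range(co$z)) + pl[3]
  in_z <- if (is.finite(model$z_extent_mm)) {
    abs(co$z - zc) <= model$z_extent_mm / 2
  } else rep(TRUE, shape[3])

  if (model$kind %in% c("couch_slab", "scanner_bed")) {
    if (is.null(posterior_mm)) {
      abort("slab hardware needs the posterior body extremum.")
    }
    top <- posterior_mm
    if (model$kind == "scanner_bed") {
      # sits directly beneath the couch slab
      top <- posterior_mm - (couch_thickness_mm %||% 0)
    }
    in_y <- co$y >= top - model$thickness_mm & co$y < top
    in_x <- if (is.finite(model$lateral_extent_mm)) {
      abs(co$x - pl[1]) <= model$lateral_extent_mm / 2
    } else rep(TRUE, shape[1])
    sel <- outer(outer(in_x, in_y, `&`), in_z, `&`)
    mu[sel] <- model$mu
  } else {
    cx <- pl[1]
    cy <- pl[2]
    r2 <- outer((co$x - cx)^2, (co$y - cy)^2, `+`)
    upper <- outer(rep(TRUE, shape[1]), co$y > cy, `&`)
    ring <- r2 >= model$arc_radius_mm^2 &
      r2 < (model$arc_radius_mm + model$thickness_mm)^2
    sel2d <- ring & upper
    sel <- outer(sel2d, in_z, `&`)
    mu[sel] <- model$mu
    if (!is.null(body) && any(sel & body$values)) {
      abort(sprintf("%s (radius %.0f mm) intersects the body; increase the radius.",
                    model$kind, model$arc_radius_mm))
    }
  }
  if (model$mu > 0 && !any(mu > 0)) {
    abort(sprintf("%s rasterizes to no voxels; hardware extends beyond the grid.",
                  model$kind))
  }
  if (!is.null(body) && model$kind %in% c("couch_slab", "scanner_bed") &&
      any(mu > 0 & body$values)) {
    abort(sprintf("%s overlaps the body mask.", model$kind))
  }
  new_volume_like(grid, mu, "MU_511KEV")
}

#' Rasterize hardware models onto a grid
#'
#' The couch slab is positioned from the posterior extremum of the body mask
#' so that its top face abuts the most posterior body voxel row; shells are
#' checked not to intersect the body.
#'
#' @param models list of [hardware_model()].
#' @param grid an [image_volume()] or [binary_mask()] defining the target
#'   grid.
#' @param body [binary_mask()] of the patient body (required for slabs).
#' @return named list of `MU_511KEV` [image_volume()] overlays.
#' @export
build_hardware <- function(models, grid, body = NULL) {
  posterior <- NULL
  if (!is.null(body)) {
    idx <- which(apply(body$values, 2, any))
    if (!length(idx)) abort("body mask is empty.")
    posterior <- body$origin[2] + (min(idx) - 1) * body$spacing[2]
  }
  couch_t <- NULL
  for (m in models) if (m$kind == "couch_slab") couch_t <- m$thickness_mm
  out <- lapply(models, rasterize_hardware, grid = grid, body = body,
                posterior_mm = posterior, couch_thickness_mm = couch_t)
  names(out) <- vapply(models, `[[`, "", "kind")
  out
}

#' Derive an external contour by thresholding
#'
#' The largest connected component of voxels at or above `threshold`, with
#' internal holes filled. Used both for the body outline of the phantom and
#' for the 0.05 g/mL external contour of the per-voxel difference analysis.
#'
#' @param img an [image_volume()] with SUV or HU semantic.
#' @param threshold scalar threshold in the image's units.
#' @return a [binary_mask()].
#' @export
derive_external_contour <- function(img, threshold) {
  assert_semantic(img, c("SUV", "HU", "ACTIVITY"))
  raw <- new_mask_like(img, img$values >= threshold)
  if (!any(raw$values)) abort("external contour is empty at this threshold.")
  fill_holes(largest_component(raw, connectivity = 26))
}
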