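# End-to-end synthetic study: cohort generation, per-patient simulation of
# the two reconstructions (same emission data, AC map with vs without
# radiotherapy hardware), delineation, metrics and metabolic analysis.

#' Study configuration
#'
#' Collects every tunable of the pipeline with the analysis defaults:
#' fixed SUV threshold 2.5 g/mL, relative threshold 40% of SUVmax with a
#' 5 mm expansion limit (0 mm towards an abutting bladder), 400-bin
#' histogram over +/-100% inside a 0.05 g/mL external contour, Bonferroni
#' alpha 0.05/8, and TLG cut-offs 125.84 g (primary only) and 341 g
#' (primary + nodal).
#'
#' @param n_patients cohort size.
#' @param shape,spacing phantom grid (voxels, mm).
#' @param body_semiaxes in-plane body ellipse semi-axes, mm (lesion and air
#'   pocket placement scales with these).
#' @param background_suv background uptake, g/mL.
#' @param n_angles projection angles.
#' @param counts_scale expected total counts per patient; `Inf` disables
#'   Poisson noise.
#' @param fixed_threshold semi-manual SUV threshold, g/mL.
#' @param threshold_fraction relative threshold fraction of SUVmax.
#' @param margin_mm expansion limit for relative thresholds, mm.
#' @param external_threshold external-contour SUV threshold, g/mL.
#' @param hist_bins,hist_lo,hist_hi histogram specification (percent).
#' @param alpha,n_tests family-wise level and number of tests.
#' @param hardware list of [hardware_model()]s omitted from CTACstd.
#' @param scanner_bed_mu,scanner_bed_thickness_mm scanner bed slab (present
#'   in both variants).
#' @param table_z_mm,landmark_z_mm coil-bridge z positioning inputs
#'   (the table position is the value carried by the scanner's private
#'   table-position tag).
#' @param std_includes_hardware control arm: when `TRUE` the "CTACstd"
#'   variant also includes the hardware, so both reconstructions are
#'   identical and every percentage difference should be ~0.
#' @param prognosis_use_study_fraction if `TRUE`, prognostic volumes reuse
#'   the study's 40% threshold GTVs instead of each rule's own fraction.
#' @param seed master seed; all stage randomness derives from it.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_patients = 10, shape = c(96, 96, 8),
                         spacing = c(2.5, 2.5, 3), body_semiaxes = c(85, 65),
                         background_suv = 1.5,
                         n_angles = 180, counts_scale = 2e7,
                         fixed_threshold = 2.5, threshold_fraction = 0.40,
                         margin_mm = 5.0, external_threshold = 0.05,
                         hist_bins = 400, hist_lo = -100, hist_hi = 100,
                         alpha = 0.05, n_tests = 8,
                         hardware = default_hardware(),
                         scanner_bed_mu = 0.002,
                         scanner_bed_thickness_mm = 10,
                         table_z_mm = 0, landmark_z_mm = 0,
                         std_includes_hardware = FALSE,
                         prognosis_use_study_fraction = FALSE,
                         seed = 1L) {
  stopifnot(n_patients >= 1, fixed_threshold > 0, threshold_fraction > 0,
            threshold_fraction < 1, margin_mm >= 0, external_threshold > 0,
            hist_bins >= 1, alpha > 0, alpha < 1, n_tests >= 1)
  structure(as.list(environment()), class = "study_config")
}

# Deterministic per-stage substream seeds (kept below 2^31).
substream_seed <- function(seed, stage, i = 0L) {
  h <- sum(utf8ToInt(stage)) %% 1000L
  (as.integer(seed) %% 100000L) * 10007L + h * 131L + as.integer(i) * 17L
}

#' Generate the cohort's phantom specifications
#'
#' One primary lesion per patient (gaussian falloff, peak SUV log-spaced so
#' that lesion SUVmean spans roughly 3-20 g/mL) and a nodal lesion in ~60%
#' of patients; an internal bowel-gas pocket; injection metadata jittered
#' around 3.5 MBq/kg with uptake times of 60-86 min. Deterministic given the
#' config seed.
#'
#' @param config a [study_config()].
#' @return list of `n_patients` lists with elements `spec` and `meta`.
#' @export
cohort_specs <- function(config) {
  n <- config$n_patients
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(config$seed, "cohort"))
  peaks <- exp(seq(log(6.5), log(38), length.out = n))[sample.int(n)]
  out <- vector("list", n)
  ax <- config$body_semiaxes[1]
  ay <- config$body_semiaxes[2]
  zmax <- (config$shape[3] - 1) / 2 * config$spacing[3]
  for (i in seq_len(n)) {
    r_prim <- runif(1, 0.16, 0.28) * ax
    prim <- tumour_spec(centre = c(runif(1, -0.14, 0.14) * ax,
                                   runif(1, -0.28, 0.03) * ay, 0),
                        radii = c(r_prim, r_prim,
                                  min(runif(1, 10, 12), zmax + 2)),
                        peak_suv = peaks[i], profile = "gaussian",
                        label = "primary",
                        abuts_bladder = if (i %% 4 == 0) "y+" else NULL)
    tumours <- list(prim)
    if (i %% 5 != 0) {
      r_nod <- runif(1, 0.10, 0.14) * ax
      tumours <- c(tumours, list(
        tumour_spec(centre = c(runif(1, 0.40, 0.52) * ax * sample(c(-1, 1), 1),
                               runif(1, 0.12, 0.32) * ay, 0),
                    radii = c(r_nod, r_nod, min(9, zmax + 2)),
                    peak_suv = runif(1, 6, 12), profile = "gaussian",
                    label = "nodal")
      ))
    }
    air <- list(list(centre = c(runif(1, -0.52, -0.42) * ax,
                                runif(1, -0.45, -0.25) * ay, 0),
                     radii = c(8, 6, min(6, zmax + 2))))
    weight <- runif(1, 58, 92)
    meta <- patient_meta(
      activity_mbq = 3.5 * weight * runif(1, 0.9, 1.1),
      weight_kg = weight,
      uptake_min = runif(1, 60, 86)
    )
    out[[i]] <- list(
      spec = phantom_spec(shape = config$shape, spacing = config$spacing,
                          body_semiaxes = config$body_semiaxes,
                          background_suv = config$background_suv,
                          tumours = tumours, air_pockets = air,
                          jitter_mm = 2,
                          seed = substream_seed(config$seed, "jitter", i)),
      meta = meta
    )
  }
  out
}

# Build the mu-map machinery for one phantom: AC variants and the true map.
build_ac_maps <- function(phantom, config) {
  ct_on_ref <- resample_ct_to_reference(phantom$ct, rigid_transform(),
                                        reference = phantom$ct)
  ct_external <- derive_external_contour(ct_on_ref, threshold = -250)
  mr_external <- phantom$body
  harmonized <- harmonize_externals(ct_on_ref, ct_external, mr_external)
  filled <- fill_internal_air(harmonized, mr_external)
  patient_mu <- hu_to_mu(filled)

  bed <- hardware_model("scanner_bed",
                        thickness_mm = config$scanner_bed_thickness_mm,
                        mu = config$scanner_bed_mu)
  models <- c(config$hardware, list(bed))
  overlays <- place_hardware(models, phantom$body,
                             table_z_mm = config$table_z_mm,
                             landmark_z_mm = config$landmark_z_mm)
  bed_overlay <- overlays[["scanner_bed"]]
  hw_overlays <- overlays[names(overlays) != "scanner_bed"]

  ac_std <- compose_ac_map(patient_mu, hw_overlays,
                           include_hardware = isTRUE(config$std_includes_hardware),
                           scanner_bed_mu = bed_overlay)
  ac_cba <- compose_ac_map(patient_mu, hw_overlays, include_hardware = TRUE,
                           scanner_bed_mu = bed_overlay)

  # The TRUE attenuation: the real patient tissue (air pockets stay air)
  # plus every physically present object.
  mu_patient_true <- hu_to_mu(phantom$ct)
  mu_true <- mu_patient_true$values
  mu_true <- pmax(mu_true, bed_overlay$values)
  for (ov in hw_overlays) mu_true <- pmax(mu_true, ov$values)
  mu_true <- new_volume_like(patient_mu, mu_true, "MU_511KEV")

  list(std = ac_std, cba = ac_cba, mu_true = mu_true)
}

#' Simulate one synthetic patient
#'
#' Builds the phantom and AC maps, simulates one emission acquisition,
#' reconstructs it twice (AC with and without the radiotherapy hardware),
#' delineates every lesion with both methods on both images and computes
#' contour and metabolic results.
#'
#' @param spec a [phantom_spec()].
#' @param meta a [patient_meta()].
#' @param config a [study_config()].
#' @param patient_id identifier used in the study tables.
#' @return a `study_record`: list with the SUV images, external contour,
#'   per-lesion contours, a `contours` comparison tibble, a `metabolic`
#'   tibble, the per-patient histogram and provenance.
#' @export
simulate_patient <- function(spec, meta, config, patient_id = "p1") {
  phantom <- build_phantom(spec, meta)
  maps <- build_ac_maps(phantom, config)
  geom <- acquisition_geometry(config$n_angles)
  params <- recon_params(counts_scale = config$counts_scale,
                         seed = substream_seed(config$seed, "poisson",
                                               sum(utf8ToInt(patient_id))))
  sino <- simulate_emission(phantom$activity, maps$mu_true, geom, params)
  suv_img <- list(
    CTACstd = to_suv(reconstruct(attenuation_correct(sino, maps$std$mu, geom),
                                 geom, params), meta),
    CTACcba = to_suv(reconstruct(attenuation_correct(sino, maps$cba$mu, geom),
                                 geom, params), meta)
  )
  external <- derive_external_contour(suv_img$CTACcba,
                                      config$external_threshold)

  contours <- list()
  contour_rows <- list()
  metab_rows <- list()
  for (li in seq_along(phantom$tumour_masks)) {
    seed_mask <- phantom$tumour_masks[[li]]
    tu <- phantom$tumours[[li]]
    overrides <- if (!is.null(tu$abuts_bladder)) {
      stats::setNames(0, tu$abuts_bladder)
    } else NULL
    lesion <- list()
    ok <- TRUE
    for (variant in c("CTACstd", "CTACcba")) {
      man <- tryCatch(
        semi_manual_gtv(suv_img[[variant]], seed_mask,
                        fixed_threshold = config$fixed_threshold,
                        lesion_label = tu$label, source_image = variant),
        error = function(e) NULL)
      if (is.null(man)) { ok <- FALSE; break }
      thr <- percentage_threshold_gtv(suv_img[[variant]], man,
                                      fraction = config$threshold_fraction,
                                      margin_mm = config$margin_mm,
                                      margin_overrides = overrides)
      lesion[[variant]] <- list(semi_manual = man, threshold = thr)
    }
    if (!ok) next
    lesion_id <- names(phantom$tumour_masks)[li]
    contours[[lesion_id]] <- lesion
    for (method in c("semi_manual", "threshold")) {
      cmp <- compare_contours(lesion$CTACstd[[method]],
                              lesion$CTACcba[[method]])
      st <- suv_stats(suv_img$CTACcba, lesion$CTACcba[[method]]$mask)
      contour_rows[[length(contour_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(patient_id = patient_id, lesion_id = lesion_id,
                       lesion_label = tu$label, method = method,
                       suv_mean_cba = st$suv_mean), cmp)
    }
    for (variant in c("CTACstd", "CTACcba")) {
      for (method in c("semi_manual", "threshold")) {
        rep <- metabolic_report(suv_img[[variant]],
                                lesion[[variant]][[method]])
        metab_rows[[length(metab_rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(patient_id = patient_id, lesion_id = lesion_id),
          rep)
      }
    }
  }

  hist_pat <- perpixel_histogram(suv_img$CTACstd, suv_img$CTACcba, external,
                                 n_bins = config$hist_bins,
                                 lo = config$hist_lo, hi = config$hist_hi)
  # Mean per-voxel difference over the same population as the histogram:
  # inside the external contour, non-zero reference, within the bin range
  # (excludes ratio blow-ups at near-zero reference voxels).
  inside <- external$values & suv_img$CTACcba$values > 0
  pct_vox <- 100 * (suv_img$CTACstd$values[inside] -
                      suv_img$CTACcba$values[inside]) /
    suv_img$CTACcba$values[inside]
  in_range <- pct_vox >= config$hist_lo & pct_vox <= config$hist_hi
  whole_image_pct <- mean(pct_vox[in_range])

  structure(list(
    patient_id = patient_id, meta = meta, spec = spec,
    tumours = phantom$tumours, tumour_masks = phantom$tumour_masks,
    suv = suv_img, external = external, gtvs = contours,
    contours = dplyr::bind_rows(contour_rows),
    metabolic = dplyr::bind_rows(metab_rows),
    histogram = hist_pat,
    whole_image_pct = whole_image_pct,
    provenance = list(seed = config$seed, counts_scale = config$counts_scale,
                      n_angles = config$n_angles)
  ), class = "study_record")
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record %s> %d lesions, whole-image mean SUV diff %.1f%%\n",
              x$patient_id, length(x$gtvs), x$whole_image_pct))
  invisible(x)
}

#' Run the full synthetic study
#'
#' Generates the cohort, simulates each patient and assembles the cohort
#' report.
#'
#' @param config a [study_config()].
#' @param progress print one line per patient.
#' @return a `study_report`; see [build_study_report()].
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  specs <- cohort_specs(config)
  records <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    if (progress) message(sprintf("patient %d/%d", i, length(specs)))
    records[[i]] <- simulate_patient(specs[[i]]$spec, specs[[i]]$meta, config,
                                     patient_id = sprintf("p%02d", i))
  }
  build_study_report(records, config)
}
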