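# AC-map construction: resampling, external harmonization, air fill,
# hardware placement and composition.

make_slab_hu <- function(n = 40, nz = 21, spacing = 2, z_from = 9, z_to = 13) {
  v <- array(-1000, c(n, n, nz))
  v[10:30, 10:30, z_from:z_to] <- 0
  image_volume(v, c(spacing, spacing, spacing), semantic = "HU")
}

test_that("identity resampling leaves values unchanged", {
  ct <- make_slab_hu()
  out <- resample_ct_to_reference(ct, rigid_transform(), ct)
  expect_equal(out$values, ct$values, tolerance = 1e-12)
})

test_that("a pure z-translation shifts the slab centroid by 10 mm", {
  ct <- make_slab_hu()
  out <- resample_ct_to_reference(ct, rigid_transform(translation_mm = c(0, 0, 10)), ct)
  zc <- function(v) {
    w <- apply(v > -500, 3, sum)
    sum(w * seq_along(w)) / sum(w)
  }
  shift_vox <- zc(out$values) - zc(ct$values)
  expect_equal(abs(shift_vox) * ct$spacing[3], 10, tolerance = 0.05)
})

test_that("a 90-degree rotation applied and inverted recovers the volume", {
  v <- array(-1000, c(31, 31, 5))
  v[8:14, 16:26, 2:4] <- 0   # asymmetric block
  ct <- image_volume(v, c(2, 2, 2), semantic = "HU")
  fwd <- resample_ct_to_reference(ct, rigid_transform(rotation_deg = c(0, 0, 90)), ct)
  back <- resample_ct_to_reference(fwd, rigid_transform(rotation_deg = c(0, 0, -90)), ct)
  interior <- array(FALSE, dim(v)); interior[3:29, 3:29, 2:4] <- TRUE
  expect_equal(back$values[interior], ct$values[interior], tolerance = 1e-6)
})

test_that("external harmonization water-fills MR-only tissue and crops", {
  ct <- make_slab_hu()
  body <- binary_mask(ct$values > -500, ct$spacing, ct$origin)
  # equal contours: crop only (here a no-op outside is already air)
  same <- harmonize_externals(ct, body, body)
  expect_equal(same$values, ct$values)
  expect_equal(attr(same, "n_waterfilled"), 0L)

  # MR external one voxel-shell larger: shell becomes water
  mr <- expand_mask(body, margin_mm = 2)
  out <- harmonize_externals(ct, body, mr)
  shell <- mr$values & !body$values
  expect_equal(attr(out, "n_waterfilled"), sum(shell))
  expect_true(all(out$values[shell] == 0))

  # MR external smaller: tissue outside it removed
  v2 <- body$values; v2[, 25:40, ] <- FALSE
  mr_small <- binary_mask(v2, ct$spacing, ct$origin)
  out2 <- harmonize_externals(ct, body, mr_small)
  expect_true(all(out2$values[!mr_small$values] == -1000))
})

test_that("internal air fill modifies exactly the pocket and is idempotent", {
  ct <- make_slab_hu()
  ext <- binary_mask(ct$values > -500, ct$spacing, ct$origin)
  hu <- ct$values
  hu[15:18, 15:19, 10:12] <- -1000   # 4*5*3 = 60-voxel gas pocket
  ct2 <- image_volume(hu, ct$spacing, ct$origin, "HU")
  out <- fill_internal_air(ct2, ext)
  expect_equal(attr(out, "n_airfilled"), 60L)
  expect_true(all(out$values[15:18, 15:19, 10:12] == 0))
  twice <- fill_internal_air(out, ext)
  expect_equal(twice$values, out$values)
  expect_equal(attr(twice, "n_airfilled"), 0L)
  # no internal air: identity
  clean <- fill_internal_air(ct, ext)
  expect_equal(clean$values, ct$values)
  # unreachable threshold: nothing modified
  none <- fill_internal_air(ct2, ext, air_hu_threshold = -2000)
  expect_equal(none$values, ct2$values)
})

test_that("table position shifts the bridge centre along z", {
  sp <- phantom_spec(shape = c(48, 48, 15), spacing = c(4, 4, 4),
                     body_semiaxes = c(60, 45))
  ph <- build_phantom(sp)
  bridge <- hardware_model("bridge_shell", 10, 0.004, arc_radius_mm = 64,
                           z_extent_mm = 20)
  zc <- function(ov) {
    w <- apply(ov$values > 0, 3, sum)
    zs <- ov$origin[3] + (seq_along(w) - 1) * ov$spacing[3]
    sum(w * zs) / sum(w)
  }
  at0 <- place_hardware(list(bridge), ph$body, table_z_mm = 0,
                        landmark_z_mm = 0)[[1]]
  # table at the landmark: centred on the grid
  expect_equal(zc(at0), 0, tolerance = 2)
  at30 <- place_hardware(list(bridge), ph$body, table_z_mm = 28,
                         landmark_z_mm = 0)[[1]]
  expect_equal(zc(at30) - zc(at0), 28, tolerance = 2)
  # zero lateral offset on a symmetric body: left-right symmetric overlay
  m <- at0$values[, , 8]
  expect_lte(sum(abs(m - m[rev(seq_len(nrow(m))), ]) > 0), 2 * ncol(m))
})

test_that("hardware that misses the grid entirely raises", {
  sp <- phantom_spec(shape = c(48, 48, 5), spacing = c(4, 4, 4),
                     body_semiaxes = c(60, 45))
  ph <- build_phantom(sp)
  far <- hardware_model("bridge_shell", 10, 0.004, arc_radius_mm = 64,
                        z_extent_mm = 20, placement = c(0, 0, 500))
  expect_error(build_hardware(list(far), ph$ct, ph$body), "beyond the grid")
})

test_that("AC-map composition is monotone and resolves overlap by maximum", {
  sp <- phantom_spec(shape = c(64, 64, 3), spacing = c(3, 3, 3),
                     body_semiaxes = c(60, 45), background_suv = 1)
  ph <- build_phantom(sp)
  patient_mu <- hu_to_mu(ph$ct)
  models <- default_hardware(bridge_radius_mm = 72, coil_radius_mm = 64)
  overlays <- place_hardware(models, ph$body)
  bed <- build_hardware(list(hardware_model("scanner_bed", 10, 0.002),
                             models[[1]]), ph$ct, ph$body)[["scanner_bed"]]

  std <- compose_ac_map(patient_mu, overlays, FALSE, scanner_bed_mu = bed)
  cba <- compose_ac_map(patient_mu, overlays, TRUE, scanner_bed_mu = bed)
  expect_equal(std$label, "CTACstd")
  expect_equal(cba$label, "CTACcba")
  # monotone: hardware only adds attenuation
  expect_true(all(cba$mu$values >= std$mu$values))
  # difference strictly inside hardware footprints
  fp <- Reduce(`|`, lapply(overlays, function(o) o$values > 0))
  dmu <- cba$mu$values - std$mu$values
  expect_true(all(dmu[!fp] == 0))
  expect_gt(sum(dmu > 0), 0)
  # provenance records every compositing step
  expect_gt(length(cba$provenance), length(std$provenance))

  # deliberate overlap: overlapping voxels take max(mu), not the sum
  slab_a <- build_hardware(list(hardware_model("couch_slab", 30, 0.005)),
                           ph$ct, ph$body)[[1]]
  slab_b <- build_hardware(list(hardware_model("couch_slab", 16, 0.003)),
                           ph$ct, ph$body)[[1]]
  both <- compose_ac_map(patient_mu, list(a = slab_a, b = slab_b), TRUE)
  overlap <- slab_a$values > 0 & slab_b$values > 0
  expect_gt(sum(overlap), 0)
  expect_true(all(both$mu$values[overlap] == 0.005))
})
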