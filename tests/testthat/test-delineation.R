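# GTV delineation: fixed-threshold semi-manual surrogate and the relative
# 40%-of-SUVmax threshold with expansion constraints.

uniform_sphere_suv <- function(n = 32, spacing = 2, radius = 10, peak = 10,
                               bg = 1) {
  co <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  vals <- array(bg, c(n, n, n))
  vals[r2 <= radius^2] <- peak
  list(suv = image_volume(vals, rep(spacing, 3), semantic = "SUV"),
       sphere = binary_mask(r2 <= radius^2, rep(spacing, 3)))
}

test_that("fixed threshold recovers a uniform sphere exactly", {
  u <- uniform_sphere_suv()
  gtv <- semi_manual_gtv(u$suv, u$sphere, fixed_threshold = 2.5)
  expect_identical(gtv$mask$values, u$sphere$values)
  expect_equal(gtv$method, "semi_manual")
})

test_that("fixed threshold grows with a global scale; relative threshold does not", {
  # gaussian lesion so the level set moves under scaling
  sp <- phantom_spec(shape = c(48, 48, 9), spacing = c(2, 2, 2),
                     body_semiaxes = c(44, 40), background_suv = 1,
                     tumours = list(tumour_spec(c(0, 0, 0), 16, 10,
                                                profile = "gaussian")))
  ph <- build_phantom(sp)
  suv <- to_suv(ph$activity, ph$meta)
  seed <- ph$tumour_masks[[1]]
  base <- semi_manual_gtv(suv, seed, 2.5)
  scaled <- suv; scaled$values <- suv$values * 1.2
  grown <- semi_manual_gtv(scaled, seed, 2.5)
  expect_gte(sum(grown$mask$values), sum(base$mask$values))
  expect_gt(sum(grown$mask$values), sum(base$mask$values))  # strictly, here

  # relative threshold: identical mask under any positive scale
  thr1 <- percentage_threshold_gtv(suv, base)
  thr2 <- percentage_threshold_gtv(scaled, base)
  expect_identical(thr1$mask$values, thr2$mask$values)
  scaled_down <- suv; scaled_down$values <- suv$values * 0.37
  thr3 <- percentage_threshold_gtv(scaled_down, base)
  expect_identical(thr1$mask$values, thr3$mask$values)
})

test_that("gaussian lesion level set matches the analytic radius", {
  # profile: bg + (peak - bg) exp(-2 r^2 / R^2); threshold T crosses at
  # r = R sqrt(log((peak - bg) / (T - bg)) / 2)
  R <- 16; peak <- 10; bg <- 1; T <- 2.5
  sp <- phantom_spec(shape = c(64, 64, 33), spacing = c(1.5, 1.5, 1.5),
                     body_semiaxes = c(46, 46), background_suv = bg,
                     tumours = list(tumour_spec(c(0, 0, 0), R, peak,
                                                profile = "gaussian")))
  ph <- build_phantom(sp)
  suv <- to_suv(ph$activity, ph$meta)
  gtv <- semi_manual_gtv(suv, ph$tumour_masks[[1]], T)
  r_analytic <- R * sqrt(log((peak - bg) / (T - bg)) / 2)
  v <- mask_volume(gtv$mask) * 1000
  r_measured <- (3 * v / (4 * pi))^(1 / 3)
  expect_lt(abs(r_measured - r_analytic), 1.5)  # within one voxel
})

test_that("lesion below threshold raises a not-FDG-avid error", {
  u <- uniform_sphere_suv(peak = 2.0)
  expect_error(semi_manual_gtv(u$suv, u$sphere, 2.5), "not FDG-avid")
})

test_that("edit hook is applied to the thresholded component", {
  u <- uniform_sphere_suv()
  shrink <- function(m) {
    v <- m$values
    v[, , 1:16] <- FALSE
    binary_mask(v, m$spacing, m$origin)
  }
  gtv <- semi_manual_gtv(u$suv, u$sphere, 2.5, edit_hook = shrink)
  expect_true(all(!gtv$mask$values[, , 1:16]))
  expect_lt(sum(gtv$mask$values), sum(u$sphere$values))
})

test_that("uniform lesion: threshold mask covers the manual mask in expansion", {
  u <- uniform_sphere_suv()   # SUVmax = SUVmean inside the sphere
  man <- semi_manual_gtv(u$suv, u$sphere, 2.5)
  thr <- percentage_threshold_gtv(u$suv, man)
  # every manual voxel exceeds 0.4 * max, so manual is contained
  expect_true(all(thr$mask$values[man$mask$values]))
})

test_that("threshold mask membership matches hand enumeration on a toy grid", {
  # 5 x 5 x 3 grid at 2 mm; manual mask is the centre voxel; margin 2 mm
  # allows a one-voxel face neighbourhood only.
  vals <- array(1, c(5, 5, 3))
  vals[3, 3, 2] <- 10
  vals[2, 3, 2] <- 6; vals[4, 3, 2] <- 3.9; vals[3, 2, 2] <- 4.1
  vals[3, 4, 2] <- 2; vals[3, 3, 1] <- 7; vals[3, 3, 3] <- 1
  vals[2, 2, 2] <- 9   # above threshold but outside the 2 mm expansion
  suv <- image_volume(vals, c(2, 2, 2), semantic = "SUV")
  man_mask <- binary_mask(array(seq_len(75) == (1 * 25 + 2 * 5 + 3),
                                c(5, 5, 3)), c(2, 2, 2))
  expect_true(man_mask$values[3, 3, 2])
  man <- structure(list(mask = man_mask, method = "semi_manual",
                        lesion_label = "primary", source_image = "CTACcba"),
                   class = "gtv_contour")
  thr <- percentage_threshold_gtv(suv, man, fraction = 0.4, margin_mm = 2)
  # T = 4; strictly above: 10 (centre), 6 (x-), 4.1 (y-), 7 (z-); NOT 3.9,
  # NOT 2, NOT the diagonal 9 (outside expansion)
  expected <- array(FALSE, c(5, 5, 3))
  expected[3, 3, 2] <- TRUE; expected[2, 3, 2] <- TRUE
  expected[3, 2, 2] <- TRUE; expected[3, 3, 1] <- TRUE
  expect_identical(thr$mask$values, expected)
})

test_that("threshold mask never escapes the allowed expansion", {
  for (s in 1:5) {
    set.seed(100 + s)
    vals <- array(runif(16 * 16 * 5, 0, 10), c(16, 16, 5))
    suv <- image_volume(vals, c(2, 2, 3), semantic = "SUV")
    mv <- array(FALSE, c(16, 16, 5)); mv[7:9, 7:10, 2:3] <- TRUE
    man <- structure(list(mask = binary_mask(mv, c(2, 2, 3)),
                          method = "semi_manual", lesion_label = "primary",
                          source_image = "CTACcba"), class = "gtv_contour")
    thr <- percentage_threshold_gtv(suv, man, margin_mm = 4)
    allowed <- expand_mask(man$mask, 4)
    expect_true(all(allowed$values[thr$mask$values]))
  }
})

test_that("a zero margin towards the bladder blocks expansion that way only", {
  u <- uniform_sphere_suv(n = 32, spacing = 2, radius = 10, peak = 10, bg = 4.5)
  man <- semi_manual_gtv(u$suv, u$sphere, 9)  # sphere itself
  # bg 4.5 > 0.4 * 10 so the whole expansion fills: asymmetry reveals margins
  thr <- percentage_threshold_gtv(u$suv, man, margin_mm = 4,
                                  margin_overrides = c("y+" = 0))
  idx <- which(thr$mask$values, arr.ind = TRUE)
  man_idx <- which(man$mask$values, arr.ind = TRUE)
  expect_gt(min(idx[, 1]), min(man_idx[, 1]) - 3)   # grew x- (by 2 voxels)
  expect_lt(min(idx[, 1]), min(man_idx[, 1]))       # did grow x-
  expect_equal(max(idx[, 2]), max(man_idx[, 2]))    # no growth y+
  expect_lt(min(idx[, 2]), min(man_idx[, 2]))       # grew y-
})

test_that("anisotropic expansion honours per-direction metric margins", {
  mv <- array(FALSE, c(11, 11, 5)); mv[6, 6, 3] <- TRUE
  m <- binary_mask(mv, c(2, 2, 3))
  ex <- expand_mask(m, margin_mm = 4, overrides = c("z-" = 0, "z+" = 3))
  idx <- which(ex$values, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(4, 8))   # +/- 4 mm = 2 voxels in x
  expect_equal(range(idx[, 3]), c(3, 4))   # nothing down, 3 mm = 1 voxel up
  # diagonal within the ellipse: (4/4)^2 alone is the x-extreme; corner
  # (2 voxels x, 1 voxel z+) has (4/4)^2 + (3/3)^2 > 1 -> excluded
  expect_false(ex$values[8, 6, 4])
})
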