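# The simplified PET forward model: projections, attenuation, FBP, SUV.

test_that("HU to mu conversion hits the water, air and midpoint values", {
  ct <- image_volume(array(c(0, -1000, -500, 1000), c(4, 1, 1)), c(1, 1, 1),
                     semantic = "HU")
  mu <- hu_to_mu(ct)
  expect_equal(mu$values[1, 1, 1], 0.0096)
  expect_equal(mu$values[2, 1, 1], 0)
  expect_equal(mu$values[3, 1, 1], 0.0048)
  # bone branch: mu_water + slope * HU
  expect_equal(mu$values[4, 1, 1], 0.0096 + 0.0000525 * 1000)
  expect_error(hu_to_mu(to_suv(image_volume(array(1, c(2, 2, 1)), c(1, 1, 1),
                                            semantic = "ACTIVITY"),
                               patient_meta())), "semantic")
})

test_that("forward projection matches analytic chord lengths of a disc", {
  R <- 40; v <- 3
  disc <- make_disc_volume(n = 96, spacing = 1, radius = R, value = v)
  geom <- acquisition_geometry(32)
  sino <- forward_project(disc, geom)
  nb <- dim(sino$values)[3]
  centre <- (nb + 1) / 2
  # central LOR: 2 R v
  expect_equal(sino$values[1, 1, centre], 2 * R * v, tolerance = 0.02)
  # off-centre LORs: 2 v sqrt(R^2 - d^2) within 2%
  for (d in c(10, 20, 30)) {  # bins are 1 mm wide
    expect_equal(sino$values[1, 1, centre + d], 2 * v * sqrt(R^2 - d^2),
                 tolerance = 0.02)
  }
  # zero volume projects to zero
  zero <- image_volume(array(0, c(16, 16, 1)), c(2, 2, 2),
                       semantic = "MU_511KEV")
  expect_true(all(forward_project(zero, geom)$values == 0))
})

test_that("emission simulation attenuates by the true mu-map", {
  disc <- make_disc_volume(n = 48, spacing = 2.5, radius = 30, value = 100)
  geom <- acquisition_geometry(48)
  mu0 <- image_volume(array(0, dim(disc$values)), disc$spacing,
                      semantic = "MU_511KEV")
  unatt <- forward_project(disc, geom)
  s0 <- simulate_emission(disc, mu0, geom, recon_params())
  expect_equal(s0$values, unatt$values)

  # a uniform horizontal mu slab crossing every vertical LOR once scales the
  # first view by exp(-mu t)
  mu_val <- 0.01; t_mm <- 20
  muv <- array(0, dim(disc$values))
  co <- (seq_len(48) - (48 + 1) / 2) * 2.5
  rows <- which(co >= -50 & co < -50 + t_mm)
  muv[, rows, ] <- mu_val
  mus <- image_volume(muv, disc$spacing, semantic = "MU_511KEV")
  s1 <- simulate_emission(disc, mus, geom, recon_params())
  view0 <- which(unatt$values[1, 1, ] > 1e-6)
  ratio <- s1$values[1, 1, view0] / unatt$values[1, 1, view0]
  expect_equal(unname(ratio), rep(exp(-mu_val * t_mm), length(view0)),
               tolerance = 0.01)
})

test_that("Poisson emission draws are seeded and reproducible", {
  disc <- make_disc_volume(n = 32, spacing = 3, radius = 30, value = 50)
  mu0 <- image_volume(array(0, dim(disc$values)), disc$spacing,
                      semantic = "MU_511KEV")
  geom <- acquisition_geometry(24)
  p <- recon_params(counts_scale = 1e5, seed = 9)
  a <- simulate_emission(disc, mu0, geom, p)
  b <- simulate_emission(disc, mu0, geom, p)
  expect_identical(a$values, b$values)
  p2 <- recon_params(counts_scale = 1e5, seed = 10)
  expect_false(identical(a$values,
                         simulate_emission(disc, mu0, geom, p2)$values))
})

test_that("attenuation correction inverts matched attenuation exactly", {
  disc <- make_disc_volume(n = 48, spacing = 2.5, radius = 40, value = 80)
  mu <- make_disc_volume(n = 48, spacing = 2.5, radius = 40, value = 0.0096,
                         semantic = "MU_511KEV")
  geom <- acquisition_geometry(48)
  unatt <- forward_project(disc, geom)
  sino <- simulate_emission(disc, mu, geom, recon_params())
  corr <- attenuation_correct(sino, mu, geom)
  expect_equal(corr$values, unatt$values, tolerance = 1e-10)
  # mu_ac = 0 is the identity
  mu0 <- image_volume(array(0, dim(disc$values)), disc$spacing,
                      semantic = "MU_511KEV")
  expect_equal(attenuation_correct(sino, mu0, geom)$values, sino$values)
})

test_that("attenuation correction factor follows exp(+path integral)", {
  # 200 mm of water: path integral 1.92, ACF = e^1.92 ~ 6.82
  n <- 60; sp <- 5
  vals <- array(0, c(n, n, 1))
  co <- (seq_len(n) - (n + 1) / 2) * sp
  vals[, abs(co) < 100, ] <- 0.0096  # slab 200 mm thick in y
  mu <- image_volume(vals, c(sp, sp, 3), semantic = "MU_511KEV")
  ones <- image_volume(array(1, c(n, n, 1)), c(sp, sp, 3),
                       semantic = "ACTIVITY")
  geom <- acquisition_geometry(16)
  sino <- new_sino <- simulate_emission(ones, mu, geom, recon_params())
  corr <- attenuation_correct(sino, mu, geom)
  nb <- dim(sino$values)[3]
  centre <- (nb + 1) / 2
  acf <- corr$values[1, 1, centre] / sino$values[1, 1, centre]
  expect_equal(acf, exp(1.92), tolerance = 0.01)
  expect_equal(exp(1.92), 6.82, tolerance = 0.001)
})

test_that("FBP recovers a uniform disc and is linear", {
  disc <- make_disc_volume(n = 96, spacing = 2.5, radius = 80, value = 1000)
  mu <- make_disc_volume(n = 96, spacing = 2.5, radius = 80, value = 0.0096,
                         semantic = "MU_511KEV")
  geom <- acquisition_geometry(180)
  sino <- simulate_emission(disc, mu, geom, recon_params())
  rec <- reconstruct(attenuation_correct(sino, mu, geom), geom)
  co <- (seq_len(96) - (96 + 1) / 2) * 2.5
  inner <- array(outer(co^2, co^2, `+`) <= (0.8 * 80)^2, c(96, 96, 1))
  expect_equal(mean(rec$values[inner]) / 1000, 1, tolerance = 0.02)

  # linearity: reconstruct(2 sino) = 2 reconstruct(sino)
  corr <- attenuation_correct(sino, mu, geom)
  corr2 <- corr; corr2$values <- 2 * corr$values
  expect_equal(reconstruct(corr2, geom)$values,
               2 * reconstruct(corr, geom)$values, tolerance = 1e-10)

  # zero sinogram reconstructs to zero
  sino0 <- attenuation_correct(sino, mu, geom); sino0$values[] <- 0
  expect_true(all(reconstruct(sino0, geom)$values == 0))
})

test_that("omitting attenuating material from the AC map lowers the image", {
  disc <- make_disc_volume(n = 64, spacing = 2.5, radius = 50, value = 500)
  body_mu <- make_disc_volume(n = 64, spacing = 2.5, radius = 50,
                              value = 0.0096, semantic = "MU_511KEV")
  # a surrounding attenuating ring present physically but absent from AC
  co <- (seq_len(64) - (64 + 1) / 2) * 2.5
  r2 <- outer(co^2, co^2, `+`)
  ringv <- array((r2 >= 60^2 & r2 < 70^2) * 0.004, c(64, 64, 1))
  mu_true <- image_volume(body_mu$values + ringv, disc$spacing,
                          semantic = "MU_511KEV")
  geom <- acquisition_geometry(120)
  sino <- simulate_emission(disc, mu_true, geom, recon_params())
  rec_full <- reconstruct(attenuation_correct(sino, mu_true, geom), geom)
  rec_miss <- reconstruct(attenuation_correct(sino, body_mu, geom), geom)
  inside <- array(r2 <= 40^2, c(64, 64, 1))
  expect_lt(mean(rec_miss$values[inside]), mean(rec_full$values[inside]))
})

test_that("mean of seeded noisy reconstructions converges to noise-free", {
  disc <- make_disc_volume(n = 32, spacing = 4, radius = 40, value = 200)
  mu <- make_disc_volume(n = 32, spacing = 4, radius = 40, value = 0.0096,
                         semantic = "MU_511KEV")
  geom <- acquisition_geometry(48)
  ref <- reconstruct(attenuation_correct(
    simulate_emission(disc, mu, geom, recon_params()), mu, geom), geom)
  n_rep <- 50
  acc <- array(0, dim(ref$values))
  for (s in seq_len(n_rep)) {
    sino <- simulate_emission(disc, mu, geom,
                              recon_params(counts_scale = 2e5, seed = s))
    acc <- acc + reconstruct(attenuation_correct(sino, mu, geom), geom)$values
  }
  co <- (seq_len(32) - (32 + 1) / 2) * 4
  inner <- array(outer(co^2, co^2, `+`) <= 30^2, c(32, 32, 1))
  mean_noisy <- mean((acc / n_rep)[inner])
  mean_ref <- mean(ref$values[inner])
  # clipping at zero makes noisy means slightly biased; allow a few percent
  expect_equal(mean_noisy / mean_ref, 1, tolerance = 0.05)
})

test_that("SUV conversion follows the body-weight convention with decay", {
  act <- image_volume(array(5000, c(2, 2, 1)), c(1, 1, 1),
                      semantic = "ACTIVITY")
  meta <- patient_meta(activity_mbq = 350, weight_kg = 70, uptake_min = 0)
  expect_equal(to_suv(act, meta)$values[1, 1, 1], 1.0)

  act2 <- image_volume(array(3500, c(2, 2, 1)), c(1, 1, 1),
                       semantic = "ACTIVITY")
  expect_equal(to_suv(act2, meta)$values[1, 1, 1], 0.7)

  # one half-life of uptake halves the decay-corrected activity
  meta_hl <- patient_meta(activity_mbq = 350, weight_kg = 70,
                          uptake_min = 109.77)
  expect_equal(to_suv(act, meta_hl)$values[1, 1, 1], 2.0)

  expect_error(patient_meta(activity_mbq = 0), "activity_mbq")
  expect_error(to_suv(act, "meta"))
})
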