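# Independent R-level oracles and tiny fixture builders. These deliberately
# avoid the package's compiled kernels so that tests compare two routes.

# Brute-force Dice from raw arrays.
dice_oracle <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Exhaustive symmetric mean surface distance. Surface = mask voxel with at
# least one non-mask 6-neighbour (borders count as outside).
surface_idx_oracle <- function(v) {
  d <- dim(v)
  out <- matrix(0, 0, 3)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!v[i, j, k]) next
    nb <- c(
      i == 1 || !v[i - 1, j, k], i == d[1] || !v[i + 1, j, k],
      j == 1 || !v[i, j - 1, k], j == d[2] || !v[i, j + 1, k],
      k == 1 || !v[i, j, k - 1], k == d[3] || !v[i, j, k + 1]
    )
    if (any(nb)) out <- rbind(out, c(i, j, k))
  }
  out
}

mda_oracle <- function(a, b, spacing) {
  sa <- surface_idx_oracle(a)
  sb <- surface_idx_oracle(b)
  pa <- sweep(sa - 1, 2, spacing, `*`)
  pb <- sweep(sb - 1, 2, spacing, `*`)
  mind <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i) {
      sqrt(min(colSums((t(q) - p[i, ])^2)))
    }, 0)
  }
  (mean(mind(pa, pb)) + mean(mind(pb, pa))) / 2
}

# Flood fill of the background from the array border (6-connectivity) by
# iterative dilation; voxels never reached are internal holes.
fill_holes_oracle <- function(v) {
  d <- dim(v)
  reach <- array(FALSE, d)
  reach[c(1, d[1]), , ] <- !v[c(1, d[1]), , ]
  reach[, c(1, d[2]), ] <- reach[, c(1, d[2]), ] | !v[, c(1, d[2]), ]
  reach[, , c(1, d[3])] <- reach[, , c(1, d[3])] | !v[, , c(1, d[3])]
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & !v
    if (identical(grown, reach)) break
    reach <- grown
  }
  v | !reach
}

# Student-t two-sided p via the regularised incomplete beta function,
# independent of stats::pt's code path through the test.
t_pvalue_oracle <- function(t, df) {
  pbeta(df / (df + t^2), df / 2, 0.5)
}

# Small centred disc/mask builders.
make_disc_volume <- function(n = 48, spacing = 2.5, radius = 40, value = 1,
                             semantic = "ACTIVITY", nz = 1) {
  co <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(co^2, co^2, `+`)
  vals <- array((r2 <= radius^2) * value, c(n, n, nz))
  image_volume(vals, c(spacing, spacing, 3), semantic = semantic)
}

make_box_mask <- function(dims, from, to, spacing = c(1, 1, 1)) {
  v <- array(FALSE, dims)
  v[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  binary_mask(v, spacing)
}

# A small, fast study configuration for end-to-end tests.
toy_config <- function(n_patients = 2, seed = 11, ...) {
  study_config(
    n_patients = n_patients, shape = c(64, 64, 2), spacing = c(3, 3, 3),
    body_semiaxes = c(60, 45), n_angles = 120, counts_scale = 5e6,
    hardware = default_hardware(bridge_radius_mm = 72, coil_radius_mm = 64),
    seed = seed, ...
  )
}
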