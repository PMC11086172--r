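test_that("subspace decomposition of a rank-1 outer product", {
  a <- complex(real = c(0.5, -0.5, 0.5, 0.5),
               imaginary = c(0, 0.0, 0, 0))   # unit norm by construction
  m <- a %*% t(a)
  dec <- eigendecompose(m)
  expect_equal(dec$values, c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(eigendecompose(matrix(0 + 0i, 4, 4))$values, rep(0, 4))
  # singular values invariant under permutation of antennas
  p <- diag(4)[c(3, 1, 4, 2), ]
  expect_equal(eigendecompose(p %*% m %*% t(p))$values, dec$values,
               tolerance = 1e-12)
  expect_error(eigendecompose(matrix(0i, 2, 3)), "square")
  expect_error(eigendecompose(matrix(c(NaN, 0, 0, 0), 2, 2)), "finite")
})

test_that("noise projector is an orthogonal projector of the right rank", {
  std <- std_geometry()
  st <- point_target_stack(1116, std$arr, std$grid, std$freqs, std$bg)
  for (i in c(1, 25, 50)) {
    np <- noise_projector(st$matrices[[i]])
    expect_equal(np$signal_dim, 1L)
    p <- np$projector
    expect_equal(p %*% p, p, tolerance = 1e-10)          # idempotent
    expect_equal(p, Conj(t(p)), tolerance = 1e-12)       # Hermitian
    expect_equal(Re(sum(diag(p))), 15, tolerance = 1e-10) # rank No - 1
    # noise subspace orthogonal to the true steering vector
    sv <- std$steer$vectors[[i]][, 1116]
    expect_lt(sqrt(sum(Mod(p %*% sv)^2)), 1e-8)
  }
  expect_error(noise_projector(matrix(0 + 0i, 4, 4)), "no signal subspace")
  expect_error(noise_projector(diag(4) + 0i, signal_dim = 4), "noise subspace")
  expect_error(noise_projector(diag(4) + 0i, tau = 2), "tau")
})

test_that("single-frequency pseudospectrum peaks at the true voxel", {
  std <- std_geometry()
  flat <- 1116
  st <- point_target_stack(flat, std$arr, std$grid, std$freqs, std$bg)
  for (i in c(1, 50)) {
    phi <- pseudospectrum(st$matrices[[i]], std$steer, i)
    expect_true(all(phi > 0))
    expect_equal(which.max(phi), flat)
    expect_gt(phi[flat], 1e6 * median(phi))  # orthogonality peak dominates
  }
})

test_that("incoherent combination equals the direct product and keeps argmax", {
  m1 <- c(1, 2, 3); m2 <- c(4, 0.5, 2)
  comb <- combine_incoherent(list(m1, m2))
  expect_equal(as.numeric(comb), m1 * m2, tolerance = 1e-12)
  one <- combine_incoherent(list(m1))
  expect_equal(as.numeric(one), m1)                  # single map: identity
  ones <- combine_incoherent(list(rep(1, 5), rep(1, 5)))
  expect_equal(as.numeric(ones), rep(1, 5))
  # per-map positive rescaling never moves the argmax
  comb2 <- combine_incoherent(list(1e7 * m1, 0.001 * m2))
  expect_equal(which.max(as.numeric(comb2)), which.max(as.numeric(comb)))
  expect_error(combine_incoherent(list(c(1, -1))), "positive")
  expect_error(combine_incoherent(list(m1, c(1, 2))), "share one grid")
  # products beyond double range stay finite via the recorded rescale
  big <- combine_incoherent(replicate(50, c(1e12, 1), simplify = FALSE))
  expect_true(all(is.finite(big)))
  expect_equal(attr(big, "log10")[1], 600)
  expect_gt(attr(big, "log10_shift"), 0)
})

test_that("slice assembly stacks 2D maps into the 3D volume", {
  g <- make_grid()
  vals <- seq_len(n_voxels(g)) / n_voxels(g)
  vol <- assemble_volume(vals, g)
  expect_equal(dim(vol$values)[3], 11L)
  expect_equal(as.numeric(vol$values), vals)
  # list-of-slices form agrees with the flat form
  slices <- lapply(seq_len(g$shape[3]), function(k)
    matrix(vals[((k - 1) * 14 * 14 + 1):(k * 14 * 14)], 14, 14))
  vol2 <- assemble_volume(slices, g)
  expect_identical(vol2$values, vol$values)
  # single-slice grid: the volume is the slice
  g1 <- make_grid(extent = list(x = c(0, 0.05), y = c(0, 0.05),
                                z = c(0, 0.01)), spacing = 0.01, n_slices = 1)
  m <- matrix(runif(25), 5, 5)
  v1 <- assemble_volume(list(m), g1)
  expect_equal(v1$values[, , 1], m)
  # global argmax = (argmax slice, argmax within slice)
  pk <- peak_voxel(vol)
  k <- pk$index[3] + 1L
  expect_equal(which.max(vol$values[, , k]),
               which.max(vol$values) - (k - 1L) * 14L * 14L)
  expect_error(assemble_volume(list(m, m), g1), "one slice per grid")
  expect_error(assemble_volume(vals[-1], g), "match the grid")
})

test_that("per-slice normalization is available for display but off by default", {
  g <- make_grid(extent = list(x = c(0, 0.03), y = c(0, 0.03), z = c(0, 0.02)),
                 spacing = 0.01, n_slices = 2)
  vals <- c(rep(2, 9), rep(8, 9))
  raw <- assemble_volume(vals, g)
  expect_equal(max(raw$values[, , 1]), 2)
  nrm <- assemble_volume(vals, g, normalize_slices = TRUE)
  expect_equal(max(nrm$values[, , 1]), 1)
  expect_equal(max(nrm$values[, , 2]), 1)
})

test_that("MUSIC and Migration both localize a noiseless point target", {
  std <- std_geometry()
  flat <- 1116
  st <- point_target_stack(flat, std$arr, std$grid, std$freqs, std$bg)
  vmu <- music_image(st, steering = std$steer)
  vmi <- migrate(st, steering = std$steer)
  expect_equal(peak_voxel(vmu)$flat, flat)
  expect_equal(peak_voxel(vmi)$flat, flat)   # same voxel for both methods
  # MUSIC has the larger dynamic range between target and clutter
  mask <- truth_mask(grid = std$grid, target_flat = flat,
                     true_center = voxel_centers(std$grid)[flat, ])
  expect_gt(smr(vmu, mask), smr(vmi, mask))
})

test_that("a zero stack migrates to a flat image and is not detected", {
  tg <- tiny_geometry()
  zero <- simulate_stack(NULL, tg$arr, tg$grid, tg$freqs,
                         contrast = complex(length.out = n_voxels(tg$grid)))
  vmi <- migrate(zero, steering = steering_field(tg$arr, tg$grid, tg$freqs,
                                                 1 + 0i))
  expect_equal(max(vmi$values), min(vmi$values))
  expect_warning(rep <- detect(vmi), "flat")
  expect_false(rep$detected)
})

test_that("binary detection separates target from noise-only volumes", {
  std <- std_geometry()
  scene <- hemorrhage_growth_scenario(c(0.025, 0.025, 0.044))
  st <- simulate_stack(scene, std$arr, std$grid, std$freqs)
  p <- mean(vapply(st$matrices, function(m) mean(Mod(m)^2), numeric(1)))
  floor30 <- sqrt(p) / 10^(30 / 20)
  # noiseless and 30 dB target volumes are detected
  expect_true(detect(music_image(st, steering = std$steer))$detected)
  noisy <- add_noise_snr(st, 30, rng_seed = 5)
  expect_true(detect(music_image(noisy, steering = std$steer))$detected)
  # seeded no-change (noise-only) Monte Carlo: never detected
  zero <- simulate_stack(NULL, std$arr, std$grid, std$freqs,
                         contrast = complex(length.out = n_voxels(std$grid)))
  for (s in 1:5) {
    nv <- music_image(add_channel_noise(zero, 0, floor30, rng_seed = s),
                      steering = std$steer)
    expect_false(detect(nv)$detected)
  }
  # calibrated-reference variant agrees
  ref <- detection_reference(std$arr, std$grid, std$freqs, floor30,
                             n_runs = 3, rng_seed = 11, steering = std$steer)
  expect_true(detect(music_image(noisy, steering = std$steer),
                     reference = ref)$detected)
  nv <- music_image(add_channel_noise(zero, 0, floor30, rng_seed = 99),
                    steering = std$steer)
  expect_false(detect(nv, reference = ref)$detected)
  expect_error(detect(nv, detection_threshold = 2), "detection_threshold")
})
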