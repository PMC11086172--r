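test_that("Green's kernel has the closed-form amplitude and reciprocity", {
  r1 <- c(0, 0, 0); r2 <- c(1, 0, 0)
  g <- green(1e9, r1, r2, 1 + 0i)
  expect_equal(Mod(g), 1 / (4 * pi), tolerance = 1e-12)
  expect_identical(green(1.3e9, c(0.1, 0, 0), c(0, 0.2, 0.05), 40 - 10i),
                   green(1.3e9, c(0, 0.2, 0.05), c(0.1, 0, 0), 40 - 10i))
  expect_error(green(1e9, r1, r1), "singular|oincident")
  expect_error(green(0, r1, r2), "freq")
})

test_that("lossy media decay faster than spherical spreading", {
  bg <- brain_blend(tissue("white_matter", "numerical"),
                    tissue("gray_matter", "numerical"))
  f <- 1e9
  g5 <- green(f, c(0, 0, 0), c(0.05, 0, 0), bg)
  g10 <- green(f, c(0, 0, 0), c(0.10, 0, 0), bg)
  expect_lt(Mod(g10), Mod(g5) * 0.5)
  # independent attenuation-constant oracle: |G(d)| = exp(Im(k) d)/(4 pi d)
  eps_c <- complex_permittivity(bg, f)
  ki <- Im(2 * pi * f / 299792458 * sqrt(eps_c))
  expect_equal(Mod(g10) / Mod(g5), 0.5 * exp(ki * 0.05), tolerance = 1e-12)
})

test_that("propagator entries equal direct kernel evaluations", {
  arr <- make_helmet(4)
  pts <- matrix(c(0.01, 0, 0.03,  -0.02, 0.01, 0.05,  0, -0.01, 0.02),
                3, 3, byrow = TRUE)
  bg <- 40 - 12i
  A <- build_propagator(1.5e9, arr, pts, bg)
  expect_equal(dim(A), c(4L, 3L))
  for (m in 1:4) for (n in 1:3)
    expect_equal(A[m, n], green(1.5e9, arr$positions[m, ], pts[n, ], bg),
                 tolerance = 1e-12)
  expect_true(all(sqrt(colSums(Mod(A)^2)) > 0))
  # lossless medium: doubling all distances halves amplitudes
  arr2 <- arr; arr2$positions <- 2 * arr$positions
  A2 <- build_propagator(1.5e9, arr2, 2 * pts, 1 + 0i)
  A1 <- build_propagator(1.5e9, arr, pts, 1 + 0i)
  expect_equal(Mod(A2), Mod(A1) / 2, tolerance = 1e-12)
})

test_that("simulated stack matches the hand-assembled Born product", {
  tg <- tiny_geometry()
  arr <- tg$arr
  arr$rx_response <- complex(real = c(1, 0.9, 1.1, 0.8),
                             imaginary = c(0, 0.1, -0.2, 0.05))
  arr$tx_response <- complex(real = c(0.7, 1, 1.2, 0.95),
                             imaginary = c(0.3, 0, 0.1, -0.1))
  dc <- complex(length.out = n_voxels(tg$grid))
  dc[c(5, 14, 20)] <- c(2 + 1i, -1 + 0i, 0.5 - 0.5i)
  st <- simulate_stack(NULL, arr, tg$grid, tg$freqs, contrast = dc,
                       background = 40 - 10i)
  vol <- prod(tg$grid$spacing)
  for (i in seq_along(tg$freqs)) {
    A <- build_propagator(as.numeric(tg$freqs)[i], arr,
                          voxel_centers(tg$grid), 40 - 10i)
    expected <- diag(arr$rx_response) %*% A %*% diag(dc * vol) %*%
      t(A) %*% diag(arr$tx_response)
    expect_equal(st$matrices[[i]], expected, tolerance = 1e-12)
  }
})

test_that("the Born model is linear, symmetric and scale-equivariant", {
  tg <- tiny_geometry()
  dc1 <- complex(length.out = n_voxels(tg$grid)); dc1[3] <- 1 + 2i
  dc2 <- complex(length.out = n_voxels(tg$grid)); dc2[22] <- -2 + 1i
  s1 <- simulate_stack(NULL, tg$arr, tg$grid, tg$freqs, contrast = dc1)
  s2 <- simulate_stack(NULL, tg$arr, tg$grid, tg$freqs, contrast = dc2)
  s12 <- simulate_stack(NULL, tg$arr, tg$grid, tg$freqs, contrast = dc1 + dc2)
  sc <- simulate_stack(NULL, tg$arr, tg$grid, tg$freqs, contrast = 3 * dc1)
  for (i in seq_along(tg$freqs)) {
    m <- s12$matrices[[i]]
    expect_equal(m, s1$matrices[[i]] + s2$matrices[[i]], tolerance = 1e-12)
    expect_equal(m, t(m), tolerance = 1e-14)          # reciprocity
    expect_equal(sc$matrices[[i]], 3 * s1$matrices[[i]], tolerance = 1e-12)
  }
})

test_that("noiseless rank equals the number of point scatterers", {
  std <- std_geometry()
  flats <- c(500, 1100, 1700)  # well-separated voxels
  for (m in 1:3) {
    st <- point_target_stack(flats[seq_len(m)], std$arr, std$grid,
                             std$freqs, std$bg)
    ranks <- vapply(st$matrices, num_rank, integer(1), rtol = 1e-8)
    expect_true(all(ranks == m), label = sprintf("M = %d", m))
  }
  # a scene with identical snapshots produces exact zeros
  sc <- hemorrhage_growth_scenario(c(0.025, 0.025, 0.044))
  same <- scattering_scene(snapshot_t1 = sc$snapshot_t1,
                           snapshot_t2 = sc$snapshot_t1)
  st0 <- simulate_stack(same, std$arr, std$grid, frequency_grid(n = 3))
  expect_true(all(vapply(st0$matrices, function(m) all(m == 0), logical(1))))
})

test_that("channel attenuation and noise are exact and seeded", {
  tg <- tiny_geometry()
  dc <- complex(length.out = n_voxels(tg$grid)); dc[10] <- 1
  st <- simulate_stack(NULL, tg$arr, tg$grid, tg$freqs, contrast = dc)
  expect_identical(add_channel_noise(st, 0, 0, 1)$matrices, st$matrices)
  att <- add_channel_noise(st, -20, 0, 1)
  for (i in seq_along(tg$freqs))
    expect_equal(att$matrices[[i]], st$matrices[[i]] * 0.1, tolerance = 1e-15)
  n1 <- add_channel_noise(st, -20, 1e-6, 7)
  n2 <- add_channel_noise(st, -20, 1e-6, 7)
  expect_identical(n1$matrices, n2$matrices)
  expect_false(identical(add_channel_noise(st, -20, 1e-6, 8)$matrices,
                         n1$matrices))
  expect_error(add_channel_noise(st, 5), "<= 0 dB")
  expect_error(add_channel_noise(st, 0, -1), "noise_floor")
})

test_that("add_noise_snr achieves the requested SNR on average", {
  tg <- tiny_geometry()
  dc <- complex(length.out = n_voxels(tg$grid)); dc[10] <- 1
  st <- simulate_stack(NULL, tg$arr, tg$grid, tg$freqs, contrast = dc)
  p_sig <- mean(vapply(st$matrices, function(m) mean(Mod(m)^2), numeric(1)))
  errs <- vapply(1:50, function(s) {
    noisy <- add_noise_snr(st, 20, rng_seed = s)
    mean(vapply(seq_along(st$matrices), function(i)
      mean(Mod(noisy$matrices[[i]] - st$matrices[[i]])^2), numeric(1)))
  }, numeric(1))
  achieved <- 10 * log10(p_sig / mean(errs))
  expect_equal(achieved, 20, tolerance = 1)
})

test_that("attenuation study reports zero error for a noiseless channel", {
  tab <- attenuation_study(noise_floor = 0, n_trials = 10, rng_seed = 1)
  expect_equal(nrow(tab), 6 * 3)   # 6 attenuation levels x 3 probe tones
  expect_equal(sort(unique(tab$alpha_db)), seq(-65, -15, by = 10))
  expect_equal(max(tab$mean_amp_err_db), 0, tolerance = 1e-10)
  expect_equal(max(tab$mean_phase_err_deg), 0, tolerance = 1e-10)
  expect_identical(attenuation_study(n_trials = 20, rng_seed = 3),
                   attenuation_study(n_trials = 20, rng_seed = 3))
})
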