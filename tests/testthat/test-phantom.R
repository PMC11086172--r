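test_that("helmet layout is on-cap, distinct and deterministic", {
  h <- make_helmet(16, 0.10, 120)
  expect_equal(nrow(h$positions), 16)
  r <- sqrt(rowSums(h$positions^2))
  expect_equal(r, rep(0.10, 16), tolerance = 1e-12)
  expect_equal(nrow(unique(round(h$positions, 9))), 16)
  expect_identical(h$positions, make_helmet(16, 0.10, 120)$positions)
  expect_true(all(h$tx_response == 1 + 0i))
  # single ring: pairwise nearest-neighbour distances equal by symmetry
  h3 <- make_helmet(3, 0.10, 120)
  d <- as.matrix(dist(h3$positions))
  offd <- d[upper.tri(d)]
  expect_equal(max(offd) - min(offd), 0, tolerance = 1e-12)
  expect_error(make_helmet(2), "at least 3")
  expect_error(make_helmet(16, cap_radius = -1), "cap_radius")
})

test_that("grid construction follows the voxel-center convention", {
  g <- make_grid()
  expect_equal(unname(g$shape[3]), 11L)       # default 11 slices
  expect_equal(unname(g$shape[1:2]), c(14L, 14L))
  g2 <- make_grid(extent = list(x = c(0, 0.2), y = c(0, 0.2), z = c(0, 0.2)),
                  spacing = 0.005)
  expect_equal(unname(g2$shape[1:2]), c(40L, 40L))
  centers <- voxel_centers(g2)
  expect_equal(unname(centers[1, ]), unname(g2$origin + g2$spacing / 2))
  # x-fastest ordering: second center moves by dx only
  expect_equal(unname(centers[2, ] - centers[1, ]),
               c(g2$spacing[["dx"]], 0, 0))
  expect_true(all(diff(g$slice_heights) > 0))
  expect_equal(length(g$slice_heights), 11L)
  expect_error(make_grid(spacing = 0), "spacing")
  expect_error(make_grid(extent = list(x = c(0, 0.001), y = c(0, 1),
                                       z = c(0, 1)), spacing = 0.01),
               "empty")
})

test_that("flat index round-trips through (i,j,k) and nearest_voxel", {
  g <- make_grid()
  for (flat in as.integer(c(1, 57, 1116, n_voxels(g)))) {
    idx <- voxel_index(g, flat)
    ctr <- g$origin + g$spacing * (as.numeric(idx) + 0.5)
    expect_identical(nearest_voxel(g, ctr), flat)
  }
})

test_that("hemorrhage growth scenario encodes a 16 mL differential", {
  sc <- hemorrhage_growth_scenario(c(0.02, 0, 0.044))
  v1 <- sc$snapshot_t1[[1]]$volume_ml
  v2 <- sc$snapshot_t2[[1]]$volume_ml
  expect_equal(v2 - v1, 16)
  expect_equal(sc$snapshot_t2[[1]]$radius, (3 * 26e-6 / (4 * pi))^(1 / 3))
  expect_equal(sc$snapshot_t2[[1]]$radius, 0.0184, tolerance = 1e-2)
  expect_lt(sc$snapshot_t1[[1]]$radius, sc$snapshot_t2[[1]]$radius)
  # blood against brain blend: positive real contrast
  g <- make_grid()
  dc <- rasterize_targets(sc, g)
  expect_true(all(Re(dc[dc != 0]) > 0))
  # deterministic
  sc2 <- hemorrhage_growth_scenario(c(0.02, 0, 0.044))
  expect_identical(rasterize_targets(sc2, g), dc)
})

test_that("negative-contrast scenario has real-negative contrast", {
  g <- make_grid()
  sc <- negative_contrast_scenario(c(0.02, 0, 0.044))
  dc <- rasterize_targets(sc, g)
  nz <- dc[dc != 0]
  expect_gt(length(nz), 0)
  expect_true(all(Re(nz) < 0))
  expect_true(all(Mod(nz) > 0))
  # background-measurement variant: empty first snapshot, full-ball support
  scb <- negative_contrast_scenario(c(0.02, 0, 0.044),
                                    differential = "background")
  expect_length(scb$snapshot_t1, 0)
  expect_gt(sum(rasterize_targets(scb, g) != 0), sum(dc != 0))
})

test_that("rasterization matches a brute-force membership oracle", {
  g <- make_grid()
  pos <- c(0.025, 0.025, 0.044)
  sc <- hemorrhage_growth_scenario(pos)
  dc <- rasterize_targets(sc, g)
  r1 <- sc$snapshot_t1[[1]]$radius
  r2 <- sc$snapshot_t2[[1]]$radius
  centers <- voxel_centers(g)
  d <- sqrt(rowSums(sweep(centers, 2, pos)^2))
  shell <- which(d <= r2 & d > r1)   # oracle: in t2 sphere but not t1
  expect_identical(which(dc != 0), shell)
  # identical snapshots cancel exactly
  same <- scattering_scene(snapshot_t1 = sc$snapshot_t1,
                           snapshot_t2 = sc$snapshot_t1)
  expect_true(all(rasterize_targets(same, g) == 0))
  # single-voxel target: one nonzero entry
  tiny <- scattering_scene(
    snapshot_t2 = list(target_inclusion(centers[500, ], 0.05,
                                        tissue("blood", "physical"))))
  expect_equal(sum(rasterize_targets(tiny, g) != 0), 1)
  # support volume approximates the differential volume within a shell of
  # boundary voxels
  vox_ml <- prod(g$spacing) * 1e6
  n_boundary <- sum(abs(d - r2) <= max(g$spacing)) +
                sum(abs(d - r1) <= max(g$spacing))
  expect_lt(abs(length(shell) * vox_ml - 16), (n_boundary + 1) * vox_ml)
  # inclusion sticking out of the grid is rejected
  expect_error(rasterize_targets(hemorrhage_growth_scenario(c(0.068, 0, 0.04)),
                                 g), "outside the grid")
})
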