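# Shared fixtures. The standard geometry (16-antenna helmet, default grid,
# 50-frequency sweep, brain-blend background) is expensive to steer, so it
# is built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

std_geometry <- function() {
  if (is.null(.fixture_env$arr)) {
    .fixture_env$arr <- make_helmet()
    .fixture_env$grid <- make_grid()
    .fixture_env$freqs <- frequency_grid()
    .fixture_env$bg <- brain_blend(tissue("white_matter", "numerical"),
                                   tissue("gray_matter", "numerical"))
    .fixture_env$steer <- steering_field(.fixture_env$arr, .fixture_env$grid,
                                         .fixture_env$freqs, .fixture_env$bg)
  }
  list(arr = .fixture_env$arr, grid = .fixture_env$grid,
       freqs = .fixture_env$freqs, bg = .fixture_env$bg,
       steer = .fixture_env$steer)
}

# Tiny geometry for cheap unit tests: 4 antennas, 27 voxels, 3 frequencies.
tiny_geometry <- function() {
  arr <- make_helmet(4)
  grid <- make_grid(extent = list(x = c(-0.03, 0.03), y = c(-0.03, 0.03),
                                  z = c(0.01, 0.04)),
                    spacing = 0.02, n_slices = 3)
  freqs <- frequency_grid(n = 3)
  list(arr = arr, grid = grid, freqs = freqs)
}

# Stack for explicit point targets at flat voxel indices with unit contrast.
point_target_stack <- function(flat, arr, grid, freqs, bg, amps = NULL) {
  dc <- complex(length.out = n_voxels(grid))
  if (is.null(amps)) amps <- rep(1 + 0i, length(flat))
  dc[flat] <- amps
  simulate_stack(NULL, arr, grid, freqs, contrast = dc, background = bg)
}

# The four standard target positions (all on voxel centers of the default
# grid), spread over quadrants and heights.
std_positions <- function() {
  list(c(0.025, 0.025, 0.044), c(-0.025, 0.025, 0.044),
       c(-0.025, -0.025, 0.052), c(0.035, -0.015, 0.036))
}

# Numerical rank: number of singular values above a relative tolerance.
num_rank <- function(m, rtol = 1e-8) {
  d <- svd(m, nu = 0, nv = 0)$d
  if (d[1] == 0) return(0L)
  sum(d >= rtol * d[1])
}
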