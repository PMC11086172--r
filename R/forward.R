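# Linear (Born) forward model: Green's kernel, propagator, differential
# multistatic scattering stack, channel attenuation/noise, stability harness.

#' Frequency grid for a multifrequency sweep
#'
#' @param fmin,fmax Band edges in Hz (defaults 1 and 2 GHz).
#' @param n Number of equispaced samples, inclusive of both edges
#'   (default 50).
#' @return An object of class `frequency_grid` (numeric vector of Hz with a
#'   class attribute).
#' @export
frequency_grid <- function(fmin = 1e9, fmax = 2e9, n = 50) {
  if (fmin <= 0 || fmax <= fmin) stop("need 0 < fmin < fmax")
  if (n < 1) stop("need at least one frequency")
  structure(seq(fmin, fmax, length.out = n), class = "frequency_grid")
}

#' Scalar Green's function of a homogeneous (possibly lossy) medium
#'
#' `G(f, ra, rb) = exp(-j k |ra - rb|) / (4 pi |ra - rb|)` with
#' `k = (2 pi f / c0) sqrt(eps_c)` and the principal square root, so that a
#' passive medium (`Im(eps_c) <= 0`) gives exponential decay with distance
#' on top of spherical spreading. This is the minimal kernel that makes the
#' linear differential scattering model and the steering vectors concrete;
#' alternatives can be plugged into [build_propagator()].
#'
#' @param freq Frequency in Hz (> 0).
#' @param r_a,r_b Length-3 coordinates in meters (must differ).
#' @param background Complex relative permittivity of the medium (or a
#'   [tissue_spec()], evaluated at `freq`).
#' @return A complex scalar.
#' @export
green <- function(freq, r_a, r_b, background = 1 + 0i) {
  if (freq <= 0) stop("freq must be > 0")
  d <- sqrt(sum((r_a - r_b)^2))
  if (d == 0) stop("coincident points: Green's function is singular")
  eps_c <- if (inherits(background, "tissue_spec"))
    complex_permittivity(background, freq) else as.complex(background)
  k <- 2 * pi * freq / C0 * sqrt(eps_c)
  exp(-1i * k * d) / (4 * pi * d)
}

#' Build the propagator matrix for one frequency
#'
#' The propagator `A` is the No x Ns matrix whose n-th column collects the
#' Green's-function responses from voxel n to each of the No antennas.
#' Normalized columns of `A` are the MUSIC steering vectors.
#'
#' @param freq Frequency in Hz.
#' @param array A [make_helmet()] array.
#' @param grid A [make_grid()] grid (or an Ns x 3 matrix of points).
#' @param background Complex relative permittivity or [tissue_spec()].
#' @param kernel Green's kernel: a function `(freq, r_a, r_b, background)`;
#'   defaults to [green()]. Only scalar kernels with the same signature are
#'   supported.
#' @return Complex No x Ns matrix.
#' @export
build_propagator <- function(freq, array, grid, background = 1 + 0i,
                             kernel = NULL) {
  stopifnot(inherits(array, "helmet_array"))
  pts <- if (inherits(grid, "voxel_grid")) voxel_centers(grid) else as.matrix(grid)
  if (nrow(pts) == 0) stop("grid is empty")
  pos <- array$positions
  if (!is.null(kernel)) {
    A <- matrix(complex(1), nrow(pos), nrow(pts))
    for (m in seq_len(nrow(pos)))
      for (n in seq_len(nrow(pts)))
        A[m, n] <- kernel(freq, pos[m, ], pts[n, ], background)
    return(A)
  }
  eps_c <- if (inherits(background, "tissue_spec"))
    complex_permittivity(background, freq) else as.complex(background)
  # vectorized distance matrix No x Ns
  d2 <- outer(rowSums(pos^2), rowSums(pts^2), "+") - 2 * pos %*% t(pts)
  d <- sqrt(pmax(d2, 0))
  if (any(d == 0))
    stop("an antenna coincides with a voxel center: singular propagator entry")
  k <- 2 * pi * freq / C0 * sqrt(eps_c)
  exp(-1i * k * d) / (4 * pi * d)
}

#' Synthesize the differential multistatic scattering stack
#'
#' For each frequency `w_i` the differential scattering matrix is the
#' linear (Born) model
#' `DeltaS(w_i) = Hr A(w_i) deltaC(w_i) A^T(w_i) Ht`,
#' with `Hr`, `Ht` the diagonal receive/transmit antenna response factors,
#' `A` the propagator, and `deltaC` the diagonal matrix of per-voxel
#' differential contrasts (uncorrelated point-scatterer reduction). Each
#' diagonal entry is the permittivity contrast change at that voxel times
#' the voxel volume, so the model is the discretized Born integral over the
#' changed region. A scene with identical snapshots yields exact zeros.
#'
#' Only voxels with nonzero differential contrast enter the product, so the
#' cost scales with the size of the changed region, not the full grid.
#'
#' @param scene A [scattering_scene()] (or `NULL` if `contrast` is given).
#' @param array A [make_helmet()] array.
#' @param grid A [make_grid()] grid.
#' @param freqs A [frequency_grid()] (or numeric Hz vector).
#' @param contrast Optional explicit per-voxel complex contrast vector
#'   (length `n_voxels(grid)`), bypassing scene rasterization; it is used
#'   unchanged at every frequency.
#' @param background Optional background permittivity override (complex or
#'   [tissue_spec()]); defaults to the scene background, or vacuum when no
#'   scene is given.
#' @return An object of class `diff_stack`: list with `matrices` (list of
#'   Nf complex No x No matrices), `freqs`, `array`, `grid`,
#'   `diag_masked = FALSE`.
#' @export
simulate_stack <- function(scene, array, grid, freqs = frequency_grid(),
                           contrast = NULL, background = NULL) {
  stopifnot(inherits(array, "helmet_array"), inherits(grid, "voxel_grid"))
  freqs <- as.numeric(freqs)
  no <- nrow(array$positions)
  hr <- array$rx_response
  ht <- array$tx_response
  vol <- prod(grid$spacing)
  centers <- voxel_centers(grid)
  mats <- vector("list", length(freqs))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    dc <- if (is.null(contrast)) rasterize_targets(scene, grid, f) else contrast
    if (length(dc) != n_voxels(grid))
      stop("contrast vector length must equal the number of voxels")
    nz <- which(dc != 0)
    if (length(nz) == 0) {
      mats[[i]] <- matrix(0 + 0i, no, no)
      next
    }
    bg <- if (!is.null(background)) background
          else if (is.null(scene)) 1 + 0i else scene$background
    A <- build_propagator(f, array, centers[nz, , drop = FALSE], bg)
    As <- A * matrix(dc[nz] * vol, no, length(nz), byrow = TRUE)
    m <- As %*% t(A)                       # A dC A^T
    mats[[i]] <- (hr * m) * matrix(ht, no, no, byrow = TRUE)  # Hr m Ht
  }
  structure(list(matrices = mats, freqs = freqs, array = array, grid = grid,
                 diag_masked = FALSE),
            class = "diff_stack")
}

#' @export
print.diff_stack <- function(x, ...) {
  no <- nrow(x$matrices[[1]])
  cat(sprintf("<diff_stack> %d frequencies (%.2f-%.2f GHz), %d x %d matrices%s\n",
              length(x$freqs), min(x$freqs) / 1e9, max(x$freqs) / 1e9, no, no,
              if (isTRUE(x$diag_masked)) " [diagonal masked]" else ""))
  invisible(x)
}

#' Apply channel attenuation and additive receiver noise
#'
#' Every matrix entry is scaled by `10^(attenuation_db / 20)` and then
#' perturbed by circularly symmetric complex Gaussian noise whose RMS
#' amplitude is `noise_floor` (a fixed receiver noise floor after a
#' fixed-gain chain). Deterministic given `rng_seed`.
#'
#' @param stack A [simulate_stack()] result.
#' @param attenuation_db Channel attenuation in dB (<= 0).
#' @param noise_floor RMS amplitude of the additive noise (>= 0, linear).
#' @param rng_seed Integer seed.
#' @return A `diff_stack` with perturbed matrices.
#' @export
add_channel_noise <- function(stack, attenuation_db = 0, noise_floor = 0,
                              rng_seed = 1L) {
  stopifnot(inherits(stack, "diff_stack"))
  if (attenuation_db > 0) stop("attenuation_db must be <= 0 dB")
  if (noise_floor < 0) stop("noise_floor must be >= 0")
  g <- 10^(attenuation_db / 20)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(rng_seed)
  stack$matrices <- lapply(stack$matrices, function(m) {
    out <- m * g
    if (noise_floor > 0) {
      n <- length(out)
      out <- out + complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) *
        (noise_floor / sqrt(2))
    }
    out
  })
  stack
}

#' Add noise at a prescribed signal-to-noise ratio
#'
#' Convenience wrapper around [add_channel_noise()]: the noise floor is set
#' so that the ratio of the stack's RMS entry amplitude to the noise RMS
#' amplitude equals `snr_db`.
#'
#' @param stack A [simulate_stack()] result.
#' @param snr_db Target SNR in dB.
#' @param rng_seed Integer seed.
#' @return A noisy `diff_stack`.
#' @export
add_noise_snr <- function(stack, snr_db, rng_seed = 1L) {
  stopifnot(inherits(stack, "diff_stack"))
  p <- mean(vapply(stack$matrices, function(m) mean(Mod(m)^2), numeric(1)))
  if (p == 0) stop("cannot set an SNR on an all-zero stack")
  floor <- sqrt(p) / 10^(snr_db / 20)
  add_channel_noise(stack, attenuation_db = 0, noise_floor = floor,
                    rng_seed = rng_seed)
}

#' Monte Carlo channel attenuation stability study
#'
#' Emulates the bench test of measuring a known channel attenuation through
#' the receiver chain: for each attenuation level `alpha` and each probe
#' frequency, a unit-amplitude tone attenuated to `10^(alpha/20)` is
#' corrupted by additive receiver noise at a fixed floor and re-measured;
#' the table reports the mean absolute error of the measured attenuation
#' (dB) and of the measured phase (degrees) over `n_trials` repetitions.
#' With a fixed noise floor the per-trial SNR falls as the attenuation
#' grows, so the errors grow toward the strongest attenuation levels.
#'
#' @param alphas Attenuation levels in dB (default -15 to -65, step -10).
#' @param noise_floor RMS amplitude of the receiver noise (linear;
#'   default 1e-4).
#' @param n_trials Trials per (alpha, frequency) cell (default 200).
#' @param rng_seed Integer seed.
#' @param probe_freqs Probe frequencies in Hz (default 1, 1.5, 2 GHz).
#' @param freq_loss_db_per_ghz Optional extra frequency-dependent channel
#'   loss in dB per GHz above the band lower edge (default 0).
#' @return A data.frame with columns `alpha_db`, `freq_hz`,
#'   `mean_amp_err_db`, `mean_phase_err_deg`, `n_trials`.
#' @export
attenuation_study <- function(alphas = seq(-15, -65, by = -10),
                              noise_floor = 1e-4, n_trials = 200,
                              rng_seed = 1L,
                              probe_freqs = c(1e9, 1.5e9, 2e9),
                              freq_loss_db_per_ghz = 0) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (noise_floor < 0) stop("noise_floor must be >= 0")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(rng_seed)
  rows <- list()
  for (a in alphas) {
    for (f in probe_freqs) {
      a_eff <- a - freq_loss_db_per_ghz * (f - min(probe_freqs)) / 1e9
      amp <- 10^(a_eff / 20)
      phi <- stats::runif(n_trials, -pi, pi)
      s <- amp * exp(1i * phi)
      if (noise_floor > 0)
        s <- s + complex(real = stats::rnorm(n_trials),
                         imaginary = stats::rnorm(n_trials)) *
          (noise_floor / sqrt(2))
      amp_err <- abs(20 * log10(Mod(s)) - a_eff)
      dphi <- Arg(s) - phi
      phase_err <- abs(atan2(sin(dphi), cos(dphi))) * 180 / pi
      rows[[length(rows) + 1L]] <- data.frame(
        alpha_db = a, freq_hz = f,
        mean_amp_err_db = mean(amp_err),
        mean_phase_err_deg = mean(phase_err),
        n_trials = n_trials)
    }
  }
  do.call(rbind, rows)
}
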