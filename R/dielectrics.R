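# Tissue dielectric properties and complex permittivity.

#' Physical constants used throughout the package
#'
#' Speed of light in vacuum (m/s) and vacuum permittivity (F/m).
#' @keywords internal
#' @name constants
NULL

C0 <- 299792458
EPS0 <- 8.8541878128e-12

#' Construct a tissue dielectric specification
#'
#' A `tissue_spec` holds the relative permittivity and conductivity of a
#' tissue at a reference frequency, together with the half-widths of their
#' measurement uncertainty intervals. These are the quantities the imaging
#' chain needs from a tissue; full dispersive (e.g. Cole-Cole) models can be
#' attached through the `dispersion` hook.
#'
#' @param name Tissue label (free string; built-in tables use
#'   `skin`, `bone`, `CSF`, `white_matter`, `gray_matter`, `brain`, `blood`).
#' @param eps_r Real relative permittivity (dimensionless) at `ref_freq`.
#' @param sigma Conductivity in S/m at `ref_freq`.
#' @param ref_freq Reference frequency in Hz (default 1 GHz).
#' @param eps_r_uncertainty,sigma_uncertainty Half-widths of the measurement
#'   uncertainty intervals (same units as `eps_r` / `sigma`); zero when the
#'   source table gives no range.
#' @param dispersion Either `"constant"` (hold `eps_r`, `sigma` at their
#'   reference values at every frequency) or a function
#'   `function(freq) list(eps_r=, sigma=)` supplying a dispersive model.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(name, eps_r, sigma, ref_freq = 1e9,
                        eps_r_uncertainty = 0, sigma_uncertainty = 0,
                        dispersion = "constant") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(eps_r) || eps_r < 1)
    stop("eps_r must be >= 1 (relative permittivity of a physical medium)")
  if (!is.numeric(sigma) || sigma < 0)
    stop("sigma must be >= 0 S/m")
  if (eps_r_uncertainty < 0 || sigma_uncertainty < 0)
    stop("uncertainty half-widths must be >= 0")
  if (!identical(dispersion, "constant") && !is.function(dispersion))
    stop("dispersion must be \"constant\" or a function(freq)")
  structure(
    list(name = name, eps_r = eps_r, sigma = sigma, ref_freq = ref_freq,
         eps_r_uncertainty = eps_r_uncertainty,
         sigma_uncertainty = sigma_uncertainty,
         dispersion = dispersion),
    class = "tissue_spec")
}

#' @export
print.tissue_spec <- function(x, ...) {
  cat(sprintf("<tissue_spec> %s: eps_r = %g +/- %g, sigma = %g +/- %g S/m @ %g GHz\n",
              x$name, x$eps_r, x$eps_r_uncertainty,
              x$sigma, x$sigma_uncertainty, x$ref_freq / 1e9))
  invisible(x)
}

#' Built-in tissue dielectric table
#'
#' Returns the table of tissue dielectric properties at 1 GHz shipped with
#' the package. Two sources are kept side by side: `"numerical"` rows are
#' the literature values used for the layered numerical head phantom
#' (skin, bone, CSF, white and gray matter), and `"physical"` rows are the
#' measured values of the liquid tissue-mimicking mixtures (pig skin, bone,
#' CSF, brain blend, blood) with their measurement-uncertainty half-widths.
#' The two sources disagree for bone and for skin conductivity; both rows
#' are kept, tagged by source, and the scenario chooses which to use.
#'
#' @param path Optional path to a user-supplied CSV with the same schema
#'   (columns `name, eps_r, sigma, eps_unc, sigma_unc, ref_freq_hz,
#'   source_table`); defaults to the packaged table.
#' @return A data.frame with one row per (tissue, source) pair.
#' @export
tissue_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tissue_properties.csv",
                        package = "incmusic", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "eps_r", "sigma", "eps_unc", "sigma_unc",
            "ref_freq_hz", "source_table")
  if (!all(need %in% names(tab)))
    stop("tissue table must have columns: ", paste(need, collapse = ", "))
  num <- setdiff(need, c("name", "source_table"))
  tab[num] <- lapply(tab[num], as.numeric)
  tab
}

#' Look up a built-in tissue
#'
#' @param name Tissue name as it appears in [tissue_table()].
#' @param source `"physical"` (measured mixture values, with uncertainties)
#'   or `"numerical"` (layered numerical-phantom values).
#' @param table Optional table from [tissue_table()] (for user overrides).
#' @return A [tissue_spec()].
#' @export
tissue <- function(name, source = c("physical", "numerical"), table = NULL) {
  source <- match.arg(source)
  tab <- if (is.null(table)) tissue_table() else table
  row <- tab[tab$name == name & tab$source_table == source, ]
  if (nrow(row) == 0L)
    stop(sprintf("no tissue '%s' with source '%s' in table", name, source))
  row <- row[1L, ]
  tissue_spec(name = row$name, eps_r = row$eps_r, sigma = row$sigma,
              ref_freq = row$ref_freq_hz,
              eps_r_uncertainty = row$eps_unc,
              sigma_uncertainty = row$sigma_unc)
}

#' Complex relative permittivity of a tissue
#'
#' Standard lossy-dielectric convention under the `exp(+j omega t)` time
#' dependence: `eps_c = eps_r - j sigma / (2 pi f eps0)`. With the default
#' `"constant"` dispersion mode, `eps_r` and `sigma` are held at their
#' reference values across the band; a user-supplied dispersion function on
#' the `tissue_spec` overrides this.
#'
#' @param tissue A [tissue_spec()].
#' @param freq Frequency in Hz (vectorized, all > 0).
#' @return Complex relative permittivity, same length as `freq`. The
#'   imaginary part is non-positive for any physical (sigma >= 0) medium.
#' @export
complex_permittivity <- function(tissue, freq) {
  stopifnot(inherits(tissue, "tissue_spec"))
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop("freq must be positive and finite")
  if (is.function(tissue$dispersion)) {
    d <- tissue$dispersion(freq)
    eps_r <- d$eps_r
    sigma <- d$sigma
  } else {
    eps_r <- tissue$eps_r
    sigma <- tissue$sigma
  }
  complex(real = eps_r, imaginary = -sigma / (2 * pi * freq * EPS0))
}

#' Blend two tissues by volume fraction
#'
#' Arithmetic volume-weighted mixing of permittivity and conductivity,
#' the simplest rule consistent with describing brain matter as a
#' white/gray blend. The default emulates brain as 75% white and 25% gray
#' matter. Uncertainty half-widths are blended with the same weights.
#'
#' @param white,gray The two constituent [tissue_spec()]s.
#' @param white_fraction Volume fraction of `white`, in \[0, 1\].
#' @param name Name for the blended tissue.
#' @return A [tissue_spec()] for the blend.
#' @export
brain_blend <- function(white, gray, white_fraction = 0.75,
                        name = "brain_blend") {
  stopifnot(inherits(white, "tissue_spec"), inherits(gray, "tissue_spec"))
  if (!is.numeric(white_fraction) || white_fraction < 0 || white_fraction > 1)
    stop("white_fraction must lie in [0, 1]")
  w <- white_fraction
  mix <- function(a, b) w * a + (1 - w) * b
  tissue_spec(
    name = name,
    eps_r = mix(white$eps_r, gray$eps_r),
    sigma = mix(white$sigma, gray$sigma),
    ref_freq = white$ref_freq,
    eps_r_uncertainty = mix(white$eps_r_uncertainty, gray$eps_r_uncertainty),
    sigma_uncertainty = mix(white$sigma_uncertainty, gray$sigma_uncertainty))
}

#' Sample a tissue within its measurement uncertainty
#'
#' Draws `eps_r` and `sigma` uniformly within their plus/minus half-width
#' intervals (the source tables give ranges, not distributions). With zero
#' uncertainties the input is returned unchanged. Deterministic given the
#' seed.
#'
#' @param tissue A [tissue_spec()].
#' @param rng_seed Integer seed.
#' @return A [tissue_spec()] with perturbed `eps_r`, `sigma` and zero
#'   uncertainties (a concrete realization).
#' @export
sample_tissue <- function(tissue, rng_seed) {
  stopifnot(inherits(tissue, "tissue_spec"))
  if (tissue$eps_r_uncertainty == 0 && tissue$sigma_uncertainty == 0)
    return(tissue)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(rng_seed)
  eps_r <- stats::runif(1, tissue$eps_r - tissue$eps_r_uncertainty,
                        tissue$eps_r + tissue$eps_r_uncertainty)
  sigma <- stats::runif(1, max(0, tissue$sigma - tissue$sigma_uncertainty),
                        tissue$sigma + tissue$sigma_uncertainty)
  tissue_spec(name = tissue$name, eps_r = eps_r, sigma = sigma,
              ref_freq = tissue$ref_freq)
}

# RNG bookkeeping: seeded helpers must not disturb the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
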