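# On-disk formats: JSON stack container, Touchstone v1 multiport snapshots,
# run configuration, reports.

STACK_SCHEMA_VERSION <- "1.0"

#' Write a differential scattering stack to a JSON container
#'
#' Plain-text container with the frequency list, real/imaginary matrix
#' parts, antenna positions, grid definition, mask policy and a schema
#' version. Numbers are written at full precision so a write/read
#' round-trip reproduces the stack to double accuracy.
#'
#' @param stack A `diff_stack`.
#' @param path Output path (`.json`).
#' @param provenance Optional named list (e.g. config hash, seed) stored
#'   verbatim in the container.
#' @export
write_stack <- function(stack, path, provenance = NULL) {
  stopifnot(inherits(stack, "diff_stack"))
  no <- nrow(stack$matrices[[1]])
  obj <- list(
    schema_version = STACK_SCHEMA_VERSION,
    freqs_hz = stack$freqs,
    n_antennas = no,
    diag_masked = isTRUE(stack$diag_masked),
    antenna_positions = stack$array$positions,
    tx_response_real = Re(stack$array$tx_response),
    tx_response_imag = Im(stack$array$tx_response),
    rx_response_real = Re(stack$array$rx_response),
    rx_response_imag = Im(stack$array$rx_response),
    grid = list(origin = stack$grid$origin,
                spacing = as.numeric(stack$grid$spacing),
                shape = as.integer(stack$grid$shape)),
    delta_s_real = lapply(stack$matrices, function(m) as.numeric(Re(m))),
    delta_s_imag = lapply(stack$matrices, function(m) as.numeric(Im(m))),
    provenance = provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a differential scattering stack from a JSON container
#'
#' @param path Path written by [write_stack()].
#' @return A `diff_stack`.
#' @export
read_stack <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version))
    stop("not a stack container: missing schema_version")
  no <- obj$n_antennas
  arr <- make_helmet()  # geometry placeholder, then overwrite
  arr$positions <- matrix(as.numeric(obj$antenna_positions), ncol = 3,
                          dimnames = list(NULL, c("x", "y", "z")))
  arr$tx_response <- complex(real = obj$tx_response_real,
                             imaginary = obj$tx_response_imag)
  arr$rx_response <- complex(real = obj$rx_response_real,
                             imaginary = obj$rx_response_imag)
  g <- obj$grid
  shape <- as.integer(g$shape)
  grid <- structure(
    list(origin = as.numeric(g$origin),
         spacing = c(dx = g$spacing[1], dy = g$spacing[2], dz = g$spacing[3]),
         shape = c(nx = shape[1], ny = shape[2], nz = shape[3]),
         slice_heights = g$origin[3] + g$spacing[3] / 2 +
           g$spacing[3] * (seq_len(shape[3]) - 1)),
    class = "voxel_grid")
  pick <- function(x, i) if (is.matrix(x)) x[i, ] else as.numeric(x[[i]])
  mats <- lapply(seq_along(obj$freqs_hz), function(i)
    matrix(complex(real = pick(obj$delta_s_real, i),
                   imaginary = pick(obj$delta_s_imag, i)), no, no))
  structure(list(matrices = mats, freqs = as.numeric(obj$freqs_hz),
                 array = arr, grid = grid,
                 diag_masked = isTRUE(obj$diag_masked),
                 provenance = obj$provenance),
            class = "diff_stack")
}

#' Write a multiport scattering snapshot as a Touchstone v1 file
#'
#' Standard Touchstone v1 text format: option line `# HZ S RI R 50`,
#' real/imaginary data, frequencies in Hz, matrix rows wrapped at four
#' parameter pairs per line as the v1 specification requires for networks
#' with more than four ports.
#'
#' @param matrices List of Nf complex N x N matrices (one snapshot).
#' @param freqs Numeric frequencies in Hz.
#' @param path Output path (conventionally `.sNp`, e.g. `.s16p`).
#' @param comment Optional comment line written at the top.
#' @export
write_touchstone <- function(matrices, freqs, path, comment = NULL) {
  n <- nrow(matrices[[1]])
  if (length(matrices) != length(freqs))
    stop("one matrix per frequency required")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("!", comment), con)
  writeLines(sprintf("! %d-port S-parameters, %d frequencies", n,
                     length(freqs)), con)
  writeLines("# HZ S RI R 50", con)
  fmt <- function(x) sprintf("%.12e", x)
  for (i in seq_along(freqs)) {
    m <- matrices[[i]]
    for (r in seq_len(n)) {
      pairs <- as.vector(rbind(Re(m[r, ]), Im(m[r, ])))
      # wrap at 4 complex pairs (8 numbers) per line
      starts <- seq(1, length(pairs), by = 8)
      for (s in starts) {
        chunk <- pairs[s:min(s + 7, length(pairs))]
        prefix <- if (r == 1 && s == 1) fmt(freqs[i]) else " "
        writeLines(paste(c(prefix, fmt(chunk)), collapse = " "), con)
      }
    }
  }
  invisible(path)
}

#' Read a Touchstone v1 multiport file
#'
#' Supports the RI/MA/DB data formats and Hz/kHz/MHz/GHz units of the v1
#' specification. The port count is taken from the file extension
#' (`.sNp`) or the `n_ports` argument.
#'
#' @param path Touchstone file path.
#' @param n_ports Port count; default parsed from the extension.
#' @return List with `freqs` (Hz) and `matrices` (list of complex N x N).
#' @export
read_touchstone <- function(path, n_ports = NULL) {
  if (is.null(n_ports)) {
    m <- regmatches(path, regexpr("\\.s([0-9]+)p$", path, ignore.case = TRUE))
    if (length(m) == 0)
      stop("cannot infer port count; pass n_ports or use a .sNp extension")
    n_ports <- as.integer(gsub("[^0-9]", "", m))
  }
  lines <- readLines(path)
  lines <- sub("!.*$", "", lines)            # strip comments
  opt <- grep("^\\s*#", lines, value = TRUE)
  unit_scale <- 1; fmtkind <- "RI"
  if (length(opt) > 0) {
    toks <- toupper(strsplit(trimws(sub("^\\s*#", "", opt[1])), "\\s+")[[1]])
    unit_scale <- switch(
      intersect(toks, c("HZ", "KHZ", "MHZ", "GHZ"))[1],
      HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9, 1)
    fk <- intersect(toks, c("RI", "MA", "DB"))
    if (length(fk) > 0) fmtkind <- fk[1]
  }
  lines <- lines[!grepl("^\\s*#", lines)]
  nums <- as.numeric(unlist(strsplit(trimws(paste(lines, collapse = " ")),
                                     "\\s+")))
  nums <- nums[!is.na(nums)]
  per_block <- 1 + 2 * n_ports^2
  if (length(nums) %% per_block != 0)
    stop(sprintf("malformed %d-port Touchstone: %d numbers is not a multiple of %d",
                 n_ports, length(nums), per_block))
  nf <- length(nums) %/% per_block
  freqs <- numeric(nf)
  mats <- vector("list", nf)
  for (i in seq_len(nf)) {
    block <- nums[((i - 1) * per_block + 1):(i * per_block)]
    freqs[i] <- block[1] * unit_scale
    d <- block[-1]
    a <- d[seq(1, length(d), by = 2)]
    b <- d[seq(2, length(d), by = 2)]
    v <- switch(fmtkind,
                RI = complex(real = a, imaginary = b),
                MA = a * exp(1i * b * pi / 180),
                DB = 10^(a / 20) * exp(1i * b * pi / 180))
    mats[[i]] <- matrix(v, n_ports, n_ports, byrow = TRUE)
  }
  if (is.unsorted(freqs)) stop("Touchstone frequencies must be increasing")
  list(freqs = freqs, matrices = mats)
}

#' Load a differential stack from a pair of Touchstone snapshots
#'
#' Reads the two time-snapshot files, checks that they agree on port count
#' and frequency grid, and forms the differential stack
#' `S(t2) - S(t1)` per frequency. Because transmission-only hardware leaves
#' the reflection coefficients unmeasured, the matrix diagonals are masked
#' (zeroed) by default.
#'
#' @param file_t1,file_t2 Touchstone paths for the two snapshots.
#' @param array Optional [make_helmet()] array to attach (default: the
#'   standard 16-antenna helmet, or rings sized to the port count).
#' @param grid Optional [make_grid()] to attach (default grid).
#' @param mask_diagonal Zero the differential diagonal (default `TRUE`).
#' @return A `diff_stack`.
#' @export
read_touchstone_pair <- function(file_t1, file_t2, array = NULL, grid = NULL,
                                 mask_diagonal = TRUE) {
  t1 <- read_touchstone(file_t1)
  t2 <- read_touchstone(file_t2)
  n1 <- nrow(t1$matrices[[1]]); n2 <- nrow(t2$matrices[[1]])
  if (n1 != n2)
    stop(sprintf("port-count mismatch: %d vs %d ports", n1, n2))
  if (length(t1$freqs) != length(t2$freqs) ||
      any(abs(t1$freqs - t2$freqs) > 1e-6 * pmax(t1$freqs, 1)))
    stop("frequency grids of the two snapshots differ")
  mats <- Map(function(a, b) {
    d <- b - a
    if (mask_diagonal) diag(d) <- 0 + 0i
    d
  }, t1$matrices, t2$matrices)
  if (is.null(array)) array <- make_helmet(n1)
  if (is.null(grid)) grid <- make_grid()
  structure(list(matrices = mats, freqs = t1$freqs, array = array,
                 grid = grid, diag_masked = mask_diagonal),
            class = "diff_stack")
}

#' Write a pseudospectrum volume to a JSON container
#'
#' Stores the log10 volume (the exact representation), slice heights and
#' the grid definition.
#'
#' @param volume A `pseudospectrum_volume`.
#' @param path Output path.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pseudospectrum_volume"))
  lg <- if (!is.null(volume$log10)) volume$log10 else log10(volume$values)
  obj <- list(schema_version = STACK_SCHEMA_VERSION,
              method = volume$method,
              shape = as.integer(volume$grid$shape),
              origin = volume$grid$origin,
              spacing = as.numeric(volume$grid$spacing),
              slice_heights_m = volume$grid$slice_heights,
              log10_volume = as.numeric(lg))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a reconstruction report as JSON
#'
#' @param report A `reconstruction_report` (optionally with metrics).
#' @param path Output path.
#' @param extra Optional named list merged into the JSON object.
#' @export
write_report <- function(report, path, extra = NULL) {
  stopifnot(inherits(report, "reconstruction_report"))
  obj <- c(list(method = report$method,
                detected = report$detected,
                statistic = report$statistic,
                reference = report$reference,
                peak_xyz_m = as.numeric(report$peak_location),
                peak_slice_index = report$peak_slice_index,
                metrics = report$metrics),
           extra)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
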