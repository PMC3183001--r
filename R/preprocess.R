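#' Preprocessing configuration
#'
#' Defaults replicate a standard linear-TOF workflow: Gaussian smoothing with
#' a 2 Da full-width-at-half-maximum kernel applied for 4 cycles, followed by
#' lower-convex-hull baseline subtraction. Smoothing always precedes baseline
#' correction.
#'
#' @param smooth_width_mz kernel FWHM in Da.
#' @param smooth_cycles number of repeated smoothing passes.
#' @param baseline `"convex_hull"` or `"none"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(smooth_width_mz = 2, smooth_cycles = 4,
                              baseline = c("convex_hull", "none")) {
  stopifnot(smooth_width_mz > 0, smooth_cycles >= 1)
  structure(list(smooth_width_mz = smooth_width_mz,
                 smooth_cycles = as.integer(smooth_cycles),
                 baseline = match.arg(baseline)),
            class = "preprocess_config")
}

check_uniform_axis <- function(mz) {
  d <- diff(mz)
  dm <- stats::median(d)
  if (any(abs(d - dm) > 1e-6 * dm))
    stop("m/z axis is not uniformly spaced; resample the spectrum onto a ",
         "uniform axis before smoothing")
  dm
}

gaussian_kernel <- function(sigma_ch) {
  r <- max(1L, ceiling(8 * sigma_ch))
  k <- stats::dnorm(seq(-r, r), sd = sigma_ch)
  k / sum(k)
}

#' Gaussian smoothing of a mass spectrum
#'
#' Convolves the spectrum with a unit-area Gaussian kernel whose FWHM is
#' `smooth_width_mz` Da, repeated `smooth_cycles` times (repeated passes
#' compose to a single Gaussian of `cycles`-fold variance). Boundaries are
#' handled by reflection, so total intensity is conserved for spectra whose
#' signal does not hug the axis ends.
#'
#' @param spectrum intensity vector on `mz`.
#' @param mz uniformly spaced m/z axis.
#' @param config a [preprocess_config()].
#' @return Smoothed intensity vector of the same length.
#' @export
gaussian_smooth <- function(spectrum, mz, config = preprocess_config()) {
  stopifnot(length(spectrum) == length(mz))
  dm <- check_uniform_axis(mz)
  sigma_ch <- (config$smooth_width_mz / (2 * sqrt(2 * log(2)))) / dm
  k <- gaussian_kernel(sigma_ch)
  r <- (length(k) - 1L) / 2L
  n <- length(spectrum)
  # reflective index map: position 0 -> 2, -1 -> 3, ...; n+1 -> n-1, ...
  reflect <- function(i) {
    i <- abs(i - 1L) %% (2L * (n - 1L))
    ifelse(i >= n, 2L * (n - 1L) - i, i) + 1L
  }
  idx <- if (n > 1L) reflect(seq(1L - r, n + r)) else rep(1L, n + 2L * r)
  y <- spectrum
  for (cycle in seq_len(config$smooth_cycles))
    y <- stats::convolve(y[idx], k, type = "filter")
  y
}

lower_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      m <- length(hull)
      a <- hull[m - 1]; b <- hull[m]
      # drop b if it lies on or above the chord a->i
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) hull <- hull[-m] else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Convex-hull baseline subtraction
#'
#' Estimates the baseline as the lower convex hull of the (m/z, intensity)
#' point set, linearly interpolated between hull vertices, and subtracts it.
#' The corrected spectrum is non-negative everywhere and exactly zero at the
#' hull vertices; adding a constant or a linear ramp to the input leaves the
#' corrected output unchanged.
#'
#' @param spectrum finite intensity vector.
#' @param mz m/z axis (strictly increasing).
#' @return A list with elements `corrected` and `baseline`.
#' @export
convex_hull_baseline <- function(spectrum, mz) {
  stopifnot(length(spectrum) == length(mz), all(is.finite(spectrum)))
  n <- length(spectrum)
  if (n == 1L)
    return(list(corrected = 0, baseline = spectrum))
  hull <- lower_hull_indices(mz, spectrum)
  baseline <- stats::approx(mz[hull], spectrum[hull], xout = mz,
                            method = "linear", rule = 2)$y
  corrected <- pmax(spectrum - baseline, 0)
  list(corrected = corrected, baseline = baseline)
}

#' Preprocess every spectrum of an imaging MS dataset
#'
#' Applies Gaussian smoothing followed by convex-hull baseline subtraction
#' (in that order) to each pixel spectrum.
#'
#' @param dataset an `msi_dataset`.
#' @param config a [preprocess_config()].
#' @return The preprocessed `msi_dataset`; attribute `"preprocessing"`
#'   records the applied steps in order.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  validate_msi_dataset(dataset)
  steps <- character(0)
  mat <- dataset$intensities
  if (config$smooth_cycles >= 1 && config$smooth_width_mz > 0) {
    for (i in seq_len(nrow(mat)))
      mat[i, ] <- gaussian_smooth(mat[i, ], dataset$mz, config)
    steps <- c(steps, "gaussian_smooth")
  }
  if (config$baseline == "convex_hull") {
    for (i in seq_len(nrow(mat)))
      mat[i, ] <- convex_hull_baseline(mat[i, ], dataset$mz)$corrected
    steps <- c(steps, "convex_hull_baseline")
  }
  dataset$intensities <- mat
  out <- validate_msi_dataset(dataset)
  attr(out, "preprocessing") <- steps
  out
}
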