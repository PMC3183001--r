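#' PCA floating-point-operation count
#'
#' Operation count of a commonly used PCA algorithm on a k-pixel,
#' N-channel dataset: `flops = 14 k N^2 + 8 N^3`. Evaluated exactly; useful
#' for contrasting raw spectra (N in the tens of thousands) with reduced
#' feature matrices (N in the hundreds), where the cubic and quadratic terms
#' collapse by orders of magnitude.
#'
#' @param k number of pixels.
#' @param N number of channels (features).
#' @return The FLOP count.
#' @export
pca_flops <- function(k, N) {
  stopifnot(k >= 0, N >= 0)
  14 * k * N^2 + 8 * N^3
}

#' Dataload of an imaging MS dataset in binary megabytes
#'
#' Raw datasets are accounted at 400 kB per spectrum; reduced datasets at 8
#' bytes per matrix entry (`k * N * 8`). The binary convention (1 kB = 1024
#' bytes, 1 MB = 1024 kB) is used throughout.
#'
#' @param k number of pixels.
#' @param N number of features (ignored for raw data).
#' @param raw whether the dataset is raw (per-spectrum accounting) or
#'   reduced (per-variable accounting).
#' @return Dataload in MB (unrounded; print at 1 decimal).
#' @export
dataload <- function(k, N = NULL, raw = FALSE) {
  if (k < 0 || (!is.null(N) && N < 0)) stop("negative input")
  if (raw) return(k * 400 / 1024)
  if (is.null(N)) stop("N is required for reduced-data dataload")
  k * N * 8 / 1024^2
}

#' Dataload / FLOP summary table for a set of datasets
#'
#' @param k vector of pixel counts.
#' @param n_raw vector (or scalar) of raw channel counts.
#' @param n_reduced vector of reduced feature counts.
#' @param labels dataset labels.
#' @return A data.frame with per-dataset and total raw/reduced dataloads
#'   (MB, 1 decimal) and reduced-data PCA FLOPs.
#' @export
resource_table <- function(k, n_raw, n_reduced, labels = NULL) {
  stopifnot(length(k) == length(n_reduced))
  n_raw <- rep_len(n_raw, length(k))
  if (is.null(labels)) labels <- paste0("tissue", seq_along(k))
  df <- data.frame(
    dataset = labels, pixels = k, channels_raw = n_raw,
    channels_reduced = n_reduced,
    dataload_raw_mb = round(vapply(k, dataload, 0, raw = TRUE), 1),
    dataload_reduced_mb = round(mapply(dataload, k, n_reduced), 1),
    flops_reduced = mapply(pca_flops, k, n_reduced),
    stringsAsFactors = FALSE)
  total <- data.frame(
    dataset = "total", pixels = sum(k), channels_raw = max(n_raw),
    channels_reduced = NA_integer_,
    dataload_raw_mb = round(sum(vapply(k, dataload, 0, raw = TRUE)), 1),
    dataload_reduced_mb = round(sum(mapply(dataload, k, n_reduced)), 1),
    flops_reduced = NA_real_, stringsAsFactors = FALSE)
  rbind(df, total)
}
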