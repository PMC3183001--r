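#' Construct an imaging MS dataset
#'
#' An `msi_dataset` holds a grid of pixel mass spectra on a shared m/z axis:
#' one spectrum per pixel of a MALDI imaging MS acquisition raster. Pixel
#' coordinates are 0-based with `x` indexing columns and `y` indexing rows;
#' imzML's 1-based convention is converted at the file boundary.
#'
#' @param coords integer matrix or data.frame with columns `x`, `y`
#'   (0-based grid coordinates, one row per pixel; must be unique).
#' @param mz strictly increasing numeric vector of m/z values (Da).
#' @param intensities numeric matrix, pixels x length(mz), finite and
#'   non-negative.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param dataset_id identifier string carried through provenance records.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensities, pixel_size_um = 100,
                        dataset_id = "dataset") {
  coords <- as_coords(coords)
  mz <- as.numeric(mz)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  obj <- structure(
    list(coords = coords, mz = mz, intensities = intensities,
         pixel_size_um = as.numeric(pixel_size_um),
         dataset_id = as.character(dataset_id)),
    class = "msi_dataset")
  validate_msi_dataset(obj)
}

as_coords <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must have two columns (x, y)")
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  coords
}

validate_msi_dataset <- function(x) {
  stopifnot(inherits(x, "msi_dataset"))
  if (anyDuplicated(paste(x$coords[, 1], x$coords[, 2])))
    stop("pixel coordinates must be unique")
  if (length(x$mz) < 1L || any(diff(x$mz) <= 0))
    stop("mz axis must be strictly increasing")
  if (nrow(x$intensities) != nrow(x$coords) ||
      ncol(x$intensities) != length(x$mz))
    stop("intensity matrix must be pixels x length(mz)")
  if (!all(is.finite(x$intensities)))
    stop("intensities must be finite")
  if (!is.finite(x$pixel_size_um) || x$pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  x
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("msi_dataset '%s': %d pixels, %d m/z channels (%.1f-%.1f Da)\n",
              x$dataset_id, nrow(x$coords), length(x$mz),
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' Construct a reduced (pixels x features) dataset
#'
#' The reduced representation of an imaging MS dataset: each pixel's spectrum
#' collapsed to integrated intensities over a panel of detected peaks. This is
#' the matrix all multivariate analyses operate on.
#'
#' @param coords pixel coordinates as for [msi_dataset()] (possibly offset
#'   after merging).
#' @param feature_mz strictly increasing feature centre masses (Da).
#' @param feature_window_ppm integration half-window per feature (ppm);
#'   recycled if scalar.
#' @param matrix_ numeric matrix, pixels x features, finite non-negative.
#' @param normalization `"none"` or `"tic"`.
#' @param provenance data.frame with columns `source_id`, `source_x`,
#'   `source_y`, `offset_x`, `offset_y` (one row per pixel); defaults to an
#'   identity record naming `dataset_id`.
#' @param dataset_id identifier string.
#' @return An object of class `reduced_dataset`.
#' @export
reduced_dataset <- function(coords, feature_mz, matrix_,
                            feature_window_ppm = 500,
                            normalization = c("none", "tic"),
                            provenance = NULL, dataset_id = "reduced") {
  coords <- as_coords(coords)
  feature_mz <- as.numeric(feature_mz)
  matrix_ <- as.matrix(matrix_)
  storage.mode(matrix_) <- "double"
  normalization <- match.arg(normalization)
  if (is.null(provenance)) {
    provenance <- data.frame(
      source_id = rep(as.character(dataset_id), nrow(coords)),
      source_x = coords[, "x"], source_y = coords[, "y"],
      offset_x = 0L, offset_y = 0L, stringsAsFactors = FALSE)
  }
  obj <- structure(
    list(coords = coords,
         features = data.frame(mz = feature_mz,
                               window_ppm = rep_len(feature_window_ppm,
                                                    length(feature_mz))),
         matrix = matrix_, normalization = normalization,
         provenance = provenance, dataset_id = as.character(dataset_id)),
    class = "reduced_dataset")
  validate_reduced_dataset(obj)
}

validate_reduced_dataset <- function(x) {
  stopifnot(inherits(x, "reduced_dataset"))
  if (anyDuplicated(paste(x$coords[, 1], x$coords[, 2])))
    stop("pixel coordinates must be unique")
  if (nrow(x$features) >= 2L && any(diff(x$features$mz) <= 0))
    stop("feature centres must be strictly increasing")
  if (nrow(x$matrix) != nrow(x$coords) || ncol(x$matrix) != nrow(x$features))
    stop("matrix must be pixels x features")
  if (!all(is.finite(x$matrix)))
    stop("matrix must be finite")
  if (nrow(x$provenance) != nrow(x$coords))
    stop("provenance must have one row per pixel")
  if (x$normalization == "tic") {
    rs <- rowSums(x$matrix)
    if (any(rs > 0 & abs(rs - 1) > 1e-9))
      stop("tic-normalized rows must sum to 1")
  }
  x
}

#' @export
print.reduced_dataset <- function(x, ...) {
  cat(sprintf(
    "reduced_dataset '%s': %d pixels x %d features, normalization=%s\n",
    x$dataset_id, nrow(x$coords), nrow(x$features), x$normalization))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param dataset_id id of the dataset the mask refers to.
#' @param coords coordinates (x, y) of the positive pixels.
#' @param label region label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(dataset_id, coords, label = "roi") {
  coords <- as_coords(coords)
  if (nrow(coords) < 1L) stop("ROI mask must contain at least one pixel")
  structure(list(dataset_id = as.character(dataset_id), coords = coords,
                 label = as.character(label)),
            class = "roi_mask")
}

#' Read an ROI mask from a CSV of pixel coordinates
#'
#' @param path CSV file with columns `x`, `y` (0-based).
#' @param dataset_id,label passed to [roi_mask()].
#' @export
read_roi <- function(path, dataset_id = "dataset", label = "roi") {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("ROI file must have columns x and y: ", path)
  roi_mask(dataset_id, df[, c("x", "y")], label = label)
}

match_roi_pixels <- function(data, roi) {
  key <- paste(data$coords[, "x"], data$coords[, "y"])
  idx <- match(paste(roi$coords[, "x"], roi$coords[, "y"]), key)
  if (anyNA(idx))
    stop("ROI mask covers pixels absent from the dataset")
  idx
}

#' Total-ion-count normalize a reduced dataset
#'
#' Divides every pixel row by its sum so each spectrum integrates to one,
#' removing per-pixel sensitivity drift. Rows whose total ion count is zero
#' (off-tissue or empty pixels) are kept as zero vectors and reported via the
#' `"zero_tic"` attribute, preserving the image geometry.
#'
#' @param data a `reduced_dataset` with `normalization == "none"`.
#' @return The normalized `reduced_dataset`; attribute `"zero_tic"` holds the
#'   row indices of zero-sum pixels.
#' @export
tic_normalize <- function(data) {
  stopifnot(inherits(data, "reduced_dataset"))
  if (data$normalization != "none")
    stop("dataset is already normalized (normalization = '",
         data$normalization, "')")
  rs <- rowSums(data$matrix)
  zero <- which(rs == 0)
  scale <- ifelse(rs > 0, rs, 1)
  data$matrix <- data$matrix / scale
  data$normalization <- "tic"
  out <- validate_reduced_dataset(data)
  attr(out, "zero_tic") <- zero
  out
}
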