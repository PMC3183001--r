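#' Feature detection / extraction configuration
#'
#' Defaults follow common linear-TOF practice for peptide/protein imaging:
#' peak picking at signal-to-noise 4 with a +/-500 ppm peak width, collation
#' of peak lists at 100 ppm, and feature integration over +/-500 ppm windows.
#'
#' @param snr_threshold minimum signal-to-noise for a detected peak.
#' @param peak_width_ppm half-width (ppm) within which nearby maxima are
#'   merged, keeping the higher.
#' @param collate_tolerance_ppm tolerance (ppm) for merging peak lists.
#' @param extract_window_ppm integration half-window (ppm) per feature.
#' @param representations which spectral representations feed peak detection.
#' @return A `reduce_config` list.
#' @export
reduce_config <- function(snr_threshold = 4, peak_width_ppm = 500,
                          collate_tolerance_ppm = 100,
                          extract_window_ppm = 500,
                          representations = c("mean", "basepeak",
                                              "var_mean_ratio",
                                              "block_max_mean")) {
  stopifnot(snr_threshold > 0, peak_width_ppm > 0,
            collate_tolerance_ppm > 0, extract_window_ppm > 0,
            length(representations) >= 1)
  structure(list(snr_threshold = snr_threshold,
                 peak_width_ppm = peak_width_ppm,
                 collate_tolerance_ppm = collate_tolerance_ppm,
                 extract_window_ppm = extract_window_ppm,
                 representations = representations),
            class = "reduce_config")
}

#' Construct a peak list
#'
#' @param mz peak centre masses (Da).
#' @param snr signal-to-noise of each peak.
#' @param source representation (or dataset) each peak was detected in.
#' @param dataset_id id of the originating dataset.
#' @return A `peak_list` data.frame (columns `mz`, `snr`, `source`), sorted
#'   by m/z.
#' @export
peak_list <- function(mz, snr = NA_real_, source = NA_character_,
                      dataset_id = "dataset") {
  df <- data.frame(mz = as.numeric(mz), snr = as.numeric(rep_len(snr, length(mz))),
                   source = as.character(rep_len(source, length(mz))),
                   stringsAsFactors = FALSE)
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_list", "data.frame"),
            dataset_id = as.character(dataset_id))
}

#' Summarizing spectral representations of an imaging MS dataset
#'
#' Computes four whole-dataset spectra used for automated peak detection. The
#' mean spectrum captures abundant, widespread signals; the base-peak spectrum
#' (per-channel maximum over pixels), the variance-to-mean-ratio spectrum and
#' the block-max-of-means spectrum (per-channel maximum over the mean spectra
#' of 8x8-pixel blocks) all emphasize localized features that a small tissue
#' region contributes but which are diluted to invisibility in the mean.
#'
#' @param dataset a preprocessed `msi_dataset`.
#' @param block integer block edge for the block-max-of-means representation.
#' @return Named list of intensity vectors on the dataset's m/z axis.
#' @export
spectral_representations <- function(dataset, block = 8L) {
  validate_msi_dataset(dataset)
  m <- dataset$intensities
  if (nrow(m) == 0L) stop("empty dataset")
  mu <- colMeans(m)
  bp <- apply(m, 2, max)
  v <- apply(m, 2, stats::var)
  if (nrow(m) == 1L) v <- rep(0, ncol(m))
  vmr <- ifelse(mu > 0, v / mu, 0)
  bid <- paste(dataset$coords[, "x"] %/% block, dataset$coords[, "y"] %/% block)
  bs <- rowsum(m, bid)
  blocks <- bs / as.vector(table(bid)[rownames(bs)])
  bmm <- apply(blocks, 2, max)
  list(mean = mu, basepeak = bp, var_mean_ratio = vmr, block_max_mean = bmm)
}

rolling_mad_noise <- function(x, frac = 0.02) {
  n <- length(x)
  w <- max(5L, round(frac * n))
  if (w %% 2L == 0L) w <- w + 1L
  w <- min(w, if (n %% 2L == 1L) n else n - 1L)
  if (w < 3L) {
    med <- rep(stats::median(x), n)
    return(list(median = med, noise = rep(stats::mad(x), n)))
  }
  med <- stats::runmed(x, w, endrule = "constant")
  list(median = med,
       noise = 1.4826 * stats::runmed(abs(x - med), w, endrule = "constant"))
}

#' Detect peaks in a spectrum
#'
#' Local-maximum picking with a sliding-window noise model: the noise at each
#' channel is 1.4826 times the running median absolute deviation of the
#' spectrum over a window spanning 2% of the axis, and a peak's
#' signal-to-noise is its height above the local running median divided by
#' that noise (so a residual background pedestal does not count as signal).
#' Maxima with signal-to-noise below `snr_threshold` are discarded;
#' surviving maxima closer than `peak_width_ppm` (relative to the lower
#' mass) are merged, keeping the higher apex.
#'
#' @param spectrum baseline-corrected non-negative intensity vector.
#' @param mz m/z axis.
#' @param config a [reduce_config()].
#' @param source label recorded per peak.
#' @param dataset_id id recorded on the returned list.
#' @return A [peak_list()].
#' @export
detect_peaks <- function(spectrum, mz, config = reduce_config(),
                         source = "spectrum", dataset_id = "dataset") {
  stopifnot(length(spectrum) == length(mz))
  n <- length(spectrum)
  if (n < 3L || diff(range(spectrum)) == 0) {
    if (diff(range(spectrum)) == 0)
      warning("constant spectrum: no peaks detectable")
    return(peak_list(numeric(0), dataset_id = dataset_id))
  }
  bg <- rolling_mad_noise(spectrum)
  noise <- bg$noise
  if (all(noise == 0)) {
    warning("zero noise estimate: no peaks reported")
    return(peak_list(numeric(0), dataset_id = dataset_id))
  }
  noise[noise == 0] <- min(noise[noise > 0])
  left <- c(-Inf, spectrum[-n])
  right <- c(spectrum[-1], -Inf)
  is_max <- spectrum > left & spectrum >= right
  # apex height from a 3-channel mean: a lower-variance estimate than the
  # single raw channel, in the spirit of apex centroiding
  apex <- as.numeric(stats::filter(spectrum, rep(1 / 3, 3), sides = 2))
  apex[c(1L, n)] <- spectrum[c(1L, n)]
  snr <- (apex - bg$median) / noise
  keep <- which(is_max & snr >= config$snr_threshold)
  if (length(keep) == 0L)
    return(peak_list(numeric(0), dataset_id = dataset_id))
  # merge maxima within peak_width_ppm, keeping the higher apex
  ord <- keep[order(spectrum[keep], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L ||
        all(abs(mz[i] - mz[kept]) / pmin(mz[i], mz[kept]) * 1e6 >
            config$peak_width_ppm))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  peak_list(mz[kept], snr[kept], source, dataset_id = dataset_id)
}

#' Detect peaks over all spectral representations of a dataset
#'
#' Runs [detect_peaks()] on each configured representation and collates the
#' per-representation lists into one dataset-specific peak list.
#'
#' @inheritParams spectral_representations
#' @param config a [reduce_config()].
#' @return A [peak_list()] for the dataset.
#' @export
detect_dataset_peaks <- function(dataset, config = reduce_config()) {
  reps <- spectral_representations(dataset)
  reps <- reps[intersect(config$representations, names(reps))]
  lists <- mapply(function(sp, nm)
    suppressWarnings(detect_peaks(sp, dataset$mz, config, source = nm,
                                  dataset_id = dataset$dataset_id)),
    reps, names(reps), SIMPLIFY = FALSE)
  collate_peaklists(lists, config$peak_width_ppm,
                    dataset_id = dataset$dataset_id)
}

#' Collate peak lists under a ppm tolerance
#'
#' Single-linkage merge: peaks from any input list whose centres differ by at
#' most `tolerance_ppm` (relative to the lower mass) join one cluster, whose
#' reported centre is the unweighted mean of the member centres. Used both to
#' pool the per-representation lists of one dataset and to build the
#' project-specific peak list across datasets (at 100 ppm).
#'
#' @param lists a list of [peak_list()] objects (each sorted).
#' @param tolerance_ppm merge tolerance in ppm.
#' @param dataset_id id for the output list.
#' @return A collated, sorted [peak_list()]; `snr` is the cluster maximum and
#'   `source` the comma-joined distinct member sources.
#' @export
collate_peaklists <- function(lists, tolerance_ppm = 100,
                              dataset_id = "project") {
  if (inherits(lists, "peak_list")) lists <- list(lists)
  all_mz <- unlist(lapply(lists, function(l) l$mz))
  if (length(all_mz) == 0L)
    return(peak_list(numeric(0), dataset_id = dataset_id))
  all_snr <- unlist(lapply(lists, function(l) l$snr))
  all_src <- unlist(lapply(lists, function(l) l$source))
  ord <- order(all_mz)
  mzs <- all_mz[ord]; snrs <- all_snr[ord]; srcs <- all_src[ord]
  gap_ppm <- diff(mzs) / mzs[-length(mzs)] * 1e6
  cluster <- cumsum(c(1, gap_ppm > tolerance_ppm))
  centers <- tapply(mzs, cluster, mean)
  snr_out <- tapply(snrs, cluster, function(s)
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
  src_out <- tapply(srcs, cluster, function(s)
    paste(sort(unique(s[!is.na(s)])), collapse = ","))
  peak_list(as.numeric(centers), as.numeric(snr_out), as.character(src_out),
            dataset_id = dataset_id)
}

#' Extract feature intensities from a dataset against a peak list
#'
#' Feature `f` of pixel `p` is the summed intensity of all m/z channels lying
#' within `window_ppm` of the peak centre. Adjacent windows may overlap, in
#' which case shared channels contribute to both features.
#'
#' @param dataset an `msi_dataset` (preprocessed).
#' @param peaks a non-empty [peak_list()].
#' @param window_ppm integration half-window in ppm.
#' @return A `reduced_dataset` (normalization `"none"`).
#' @export
extract_features <- function(dataset, peaks, window_ppm = 500) {
  validate_msi_dataset(dataset)
  if (nrow(peaks) == 0L) stop("peak list is empty")
  F <- nrow(peaks)
  out <- matrix(0, nrow(dataset$intensities), F)
  for (f in seq_len(F)) {
    ctr <- peaks$mz[f]
    half <- ctr * window_ppm * 1e-6
    ch <- which(dataset$mz >= ctr - half & dataset$mz <= ctr + half)
    if (length(ch) == 0L) {
      warning("integration window around m/z ", format(ctr),
              " contains no channel; feature set to 0")
    } else {
      out[, f] <- rowSums(dataset$intensities[, ch, drop = FALSE])
    }
  }
  reduced_dataset(dataset$coords, peaks$mz, out,
                  feature_window_ppm = window_ppm,
                  dataset_id = dataset$dataset_id)
}

#' Reduce one imaging MS dataset end to end
#'
#' Representations -> per-representation peak detection -> collation ->
#' feature extraction, with the defaults of [reduce_config()].
#'
#' @inheritParams detect_dataset_peaks
#' @return A list with elements `reduced` (the `reduced_dataset`) and
#'   `peaks` (the dataset-specific [peak_list()]).
#' @export
reduce_dataset <- function(dataset, config = reduce_config()) {
  peaks <- detect_dataset_peaks(dataset, config)
  list(reduced = extract_features(dataset, peaks, config$extract_window_ppm),
       peaks = peaks)
}

#' Merge reduced datasets into one project dataset
#'
#' Places the datasets side by side on a single virtual grid, separated by a
#' fixed horizontal gutter, so the multivariate methods can be applied to all
#' tissues simultaneously. Provenance records each pixel's source dataset and
#' the applied offset, making the merge losslessly invertible with
#' [unmerge_dataset()]. All inputs must have been extracted against the same
#' project peak list.
#'
#' @param reduced_list list of `reduced_dataset` objects sharing one feature
#'   panel.
#' @param gutter horizontal gap (pixels) between consecutive datasets.
#' @param dataset_id id for the merged dataset.
#' @return A merged `reduced_dataset`; total pixels = sum of the inputs.
#' @export
merge_datasets <- function(reduced_list, gutter = 5L, dataset_id = "project") {
  stopifnot(length(reduced_list) >= 1)
  f0 <- reduced_list[[1]]$features$mz
  for (d in reduced_list)
    if (length(d$features$mz) != length(f0) ||
        any(d$features$mz != f0))
      stop("datasets were not extracted against the same project peak list")
  norm0 <- reduced_list[[1]]$normalization
  if (!all(vapply(reduced_list, function(d) d$normalization, "") == norm0))
    stop("datasets have mixed normalization states")
  x_off <- 0L
  parts <- vector("list", length(reduced_list))
  for (i in seq_along(reduced_list)) {
    d <- reduced_list[[i]]
    shift_x <- x_off - min(d$coords[, "x"])
    shift_y <- -min(d$coords[, "y"])
    coords <- cbind(x = d$coords[, "x"] + shift_x,
                    y = d$coords[, "y"] + shift_y)
    prov <- data.frame(source_id = d$provenance$source_id,
                       source_x = d$provenance$source_x,
                       source_y = d$provenance$source_y,
                       offset_x = d$provenance$offset_x + shift_x,
                       offset_y = d$provenance$offset_y + shift_y,
                       stringsAsFactors = FALSE)
    parts[[i]] <- list(coords = coords, matrix = d$matrix, prov = prov)
    x_off <- max(coords[, "x"]) + 1L + as.integer(gutter)
  }
  reduced_dataset(do.call(rbind, lapply(parts, `[[`, "coords")),
                  f0,
                  do.call(rbind, lapply(parts, `[[`, "matrix")),
                  feature_window_ppm = reduced_list[[1]]$features$window_ppm,
                  normalization = norm0,
                  provenance = do.call(rbind, lapply(parts, `[[`, "prov")),
                  dataset_id = dataset_id)
}

#' Split a merged project dataset back into its source datasets
#'
#' Inverts [merge_datasets()] using the recorded per-pixel provenance.
#'
#' @param merged a merged `reduced_dataset`.
#' @return Named list of `reduced_dataset` objects, one per source id.
#' @export
unmerge_dataset <- function(merged) {
  validate_reduced_dataset(merged)
  ids <- unique(merged$provenance$source_id)
  out <- lapply(ids, function(id) {
    sel <- merged$provenance$source_id == id
    prov <- merged$provenance[sel, , drop = FALSE]
    reduced_dataset(cbind(x = prov$source_x, y = prov$source_y),
                    merged$features$mz,
                    merged$matrix[sel, , drop = FALSE],
                    feature_window_ppm = merged$features$window_ppm,
                    normalization = merged$normalization,
                    provenance = data.frame(source_id = prov$source_id,
                                            source_x = prov$source_x,
                                            source_y = prov$source_y,
                                            offset_x = 0L, offset_y = 0L,
                                            stringsAsFactors = FALSE),
                    dataset_id = id)
  })
  names(out) <- ids
  out
}

#' Write a peak list as TSV
#' @param peaks a [peak_list()].
#' @param path output path.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
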