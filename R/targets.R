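#' Build a supervised target image from a region of interest
#'
#' The mean spectrum over the ROI pixels is computed, its principal peaks
#' detected at signal-to-noise greater than `snr_threshold`, and the images
#' of those peaks extracted over the whole dataset and algebraically summed.
#' The resulting target image (and its peak spectrum) captures the unrefined
#' heterogeneity of the region and serves as ground truth for judging the
#' unsupervised methods.
#'
#' @param data an `msi_dataset` or `reduced_dataset`.
#' @param roi an [roi_mask()] over the dataset's pixels.
#' @param snr_threshold minimum signal-to-noise of retained peaks.
#' @param window_ppm integration half-window (profile data only).
#' @return A `target_image`: list with `image` (vector over all dataset
#'   pixels), `coords`, `spectrum` (a [peak_list()] of the principal peaks),
#'   `profile` (the ROI mean profile on the feature/channel axis), `label`.
#' @export
make_target <- function(data, roi, snr_threshold = 5, window_ppm = 500) {
  UseMethod("make_target")
}

#' @export
make_target.msi_dataset <- function(data, roi, snr_threshold = 5,
                                    window_ppm = 500) {
  idx <- match_roi_pixels(data, roi)
  roi_mean <- colMeans(data$intensities[idx, , drop = FALSE])
  cfg <- reduce_config(snr_threshold = snr_threshold)
  peaks <- detect_peaks(roi_mean, data$mz, cfg, source = roi$label,
                        dataset_id = data$dataset_id)
  if (nrow(peaks) == 0L)
    stop("no peaks above S/N ", snr_threshold, " in ROI '", roi$label, "'")
  red <- extract_features(data, peaks, window_ppm)
  structure(list(image = rowSums(red$matrix), coords = data$coords,
                 spectrum = peaks, profile = roi_mean, label = roi$label),
            class = "target_image")
}

#' @export
make_target.reduced_dataset <- function(data, roi, snr_threshold = 5,
                                        window_ppm = 500) {
  idx <- match_roi_pixels(data, roi)
  profile <- colMeans(data$matrix[idx, , drop = FALSE])
  # features are already peaks: select by S/N against the panel-wide
  # MAD-based noise level of the ROI profile, measuring height above the
  # panel median so the typical feature level does not count as signal
  med <- stats::median(profile)
  noise <- 1.4826 * stats::mad(profile, constant = 1)
  if (noise == 0) noise <- max(profile - med, 1e-12) / 1e6
  snr <- (profile - med) / noise
  sel <- which(snr > snr_threshold)
  if (length(sel) == 0L)
    stop("no features above S/N ", snr_threshold, " in ROI '", roi$label,
         "'")
  structure(list(image = rowSums(data$matrix[, sel, drop = FALSE]),
                 coords = data$coords,
                 spectrum = peak_list(data$features$mz[sel], snr[sel],
                                      roi$label,
                                      dataset_id = data$dataset_id),
                 profile = profile, label = roi$label),
            class = "target_image")
}

best_component_match <- function(target_img, cs) {
  rs <- vapply(seq_len(ncol(cs$scores)), function(k) {
    r <- suppressWarnings(unfolded_pearson(target_img, cs$scores[, k]))
    if (cs$sign_definite) r else abs(r)
  }, numeric(1))
  k <- which.max(rs)
  flip <- !cs$sign_definite &&
    suppressWarnings(unfolded_pearson(target_img, cs$scores[, k])) < 0
  list(index = k, r = rs[k], flip = flip)
}

#' Correlate target images with component and agreement outputs
#'
#' For every target, finds the best-matching component of each method (by
#' unfolded Pearson correlation of the images; both signs tried for
#' sign-indefinite methods) and the best-matching continuous agreement plot,
#' and reports the image and spectrum correlations. Spectrum correlations
#' compare the basepeak-normalized target profile with the (sign-oriented,
#' basepeak-normalized) loading or consensus spectrum on the shared feature
#' panel.
#'
#' @param targets list of [make_target()] outputs.
#' @param components named list of [component_set()]s.
#' @param plots list of agreement plots (e.g. `run_agreement()$plots`).
#' @return A list: `table` (one row per target x method, with columns
#'   `target`, `method`, `component`, `image_r`, `spectrum_r`) and `summary`
#'   (per-method mean and sd of the image correlations).
#' @export
validate_against_targets <- function(targets, components, plots) {
  rows <- list()
  for (t in targets) {
    tprof <- basepeak_norm(t$profile)
    for (m in names(components)) {
      cs <- components[[m]]
      bm <- best_component_match(t$image, cs)
      sp_r <- suppressWarnings(unfolded_pearson(
        tprof, basepeak_norm(oriented_loading(cs, bm$index, bm$flip))))
      rows[[length(rows) + 1L]] <- data.frame(
        target = t$label, method = m, component = bm$index,
        image_r = bm$r, spectrum_r = sp_r, stringsAsFactors = FALSE)
    }
    if (length(plots) > 0) {
      rs <- vapply(plots, function(p)
        suppressWarnings(unfolded_pearson(t$image, p$continuous)),
        numeric(1))
      b <- which.max(rs)
      sp_r <- suppressWarnings(unfolded_pearson(
        tprof, plots[[b]]$consensus_spectrum))
      rows[[length(rows) + 1L]] <- data.frame(
        target = t$label, method = "agreement", component = b,
        image_r = rs[b], spectrum_r = sp_r, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  agg_mean <- tapply(tab$image_r, tab$method, mean)
  agg_sd <- tapply(tab$image_r, tab$method, stats::sd)
  summary <- data.frame(method = names(agg_mean),
                        mean_image_r = as.numeric(agg_mean),
                        sd_image_r = as.numeric(agg_sd),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}

#' Jaccard index of two pixel sets
#'
#' @param a,b logical vectors over the same pixel universe.
#' @return `|a & b| / |a | b|`; 1 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
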