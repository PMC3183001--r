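#' Specification for a synthetic imaging MS phantom
#'
#' Describes a rectangular pixel grid carrying nodular regions (ellipses)
#' over a background, a shared peptide/protein peak panel present everywhere
#' and a small differential panel per nodule, plus the nuisance processes of
#' a linear-TOF acquisition: an exponentially decaying chemical baseline,
#' additive Gaussian noise clipped at zero, and a per-pixel log-normal
#' total-ion-count drift. Defaults emulate an intermediate-grade sarcoma
#' style dataset: a ~3000-pixel grid with 3 spectrally distinct nodules,
#' ~100 features in m/z 2000-25000, and differential peaks at
#' signal-to-noise 8.
#'
#' @param grid `c(nx, ny)` pixel grid dimensions.
#' @param regions list of ellipses `list(cx, cy, rx, ry)` (pixel units);
#'   must lie inside the grid and not overlap.
#' @param n_shared number of shared-panel peaks.
#' @param n_diff number of differential peaks per region.
#' @param mz_range m/z interval the peaks occupy (Da).
#' @param shared_intensity `c(meanlog, sdlog)` of the log-normal
#'   distribution shared-peak mean intensities are drawn from (once, from
#'   the spec's seed). The default puts most shared peaks near the
#'   detection limit with a right tail of large uniform contributors, the
#'   typical dynamic range of a reduced MALDI peak panel.
#' @param diff_intensity mean intensity of every differential peak.
#' @param peak_width_ppm Gaussian peak FWHM in ppm (profile phantoms).
#' @param baseline_amplitude,baseline_decay exponential baseline
#'   `a * exp(-(mz - min) / decay)` (profile phantoms).
#' @param noise_sd additive Gaussian noise standard deviation. The default
#'   puts the weakest (median-scale) shared peaks at the S/N ~ 4 detection
#'   threshold a reduced panel is built with, and the differential peaks at
#'   S/N `diff_intensity / noise_sd` = 32.
#' @param tic_sd standard deviation of the log-normal per-pixel TIC factor
#'   (on the log scale).
#' @param mz_step axis spacing in Da (profile phantoms).
#' @param seed mandatory integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(60L, 50L),
                         regions = list(list(cx = 15, cy = 12, rx = 8, ry = 6),
                                        list(cx = 43, cy = 14, rx = 7, ry = 7),
                                        list(cx = 30, cy = 37, rx = 10, ry = 7)),
                         n_shared = 85L, n_diff = 5L,
                         mz_range = c(2000, 25000),
                         shared_intensity = c(log(10), 0.6),
                         diff_intensity = 80,
                         peak_width_ppm = 800,
                         baseline_amplitude = 30, baseline_decay = 3000,
                         noise_sd = 2.5, tic_sd = 0.15,
                         mz_step = 1, seed) {
  if (missing(seed)) stop("phantom_spec requires an explicit seed")
  stopifnot(length(grid) == 2, all(grid >= 1), n_shared >= 0, n_diff >= 0,
            mz_range[1] >= 2000, mz_range[2] <= 25000,
            noise_sd >= 0, tic_sd >= 0)
  for (r in regions) {
    if (r$cx - r$rx < 0 || r$cx + r$rx > grid[1] - 1 ||
        r$cy - r$ry < 0 || r$cy + r$ry > grid[2] - 1)
      stop("region ellipse extends outside the grid")
  }
  structure(list(grid = as.integer(grid), regions = regions,
                 n_shared = as.integer(n_shared), n_diff = as.integer(n_diff),
                 mz_range = mz_range, shared_intensity = shared_intensity,
                 diff_intensity = diff_intensity,
                 peak_width_ppm = peak_width_ppm,
                 baseline_amplitude = baseline_amplitude,
                 baseline_decay = baseline_decay,
                 noise_sd = noise_sd, tic_sd = tic_sd, mz_step = mz_step,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# deterministic peak panel layout: peaks spread over mz_range on a jittered
# grid, differential peaks interleaved between shared ones
phantom_panel <- function(spec) {
  n_regions <- length(spec$regions)
  n_total <- spec$n_shared + n_regions * spec$n_diff
  with_seed(spec$seed, {
    lo <- spec$mz_range[1] * 1.02
    hi <- spec$mz_range[2] * 0.98
    # log-spaced slots keep ppm separations roughly uniform across the axis
    slots <- exp(seq(log(lo), log(hi), length.out = n_total))
    jit <- stats::runif(n_total, -0.1, 0.1) * c(0, diff(slots))
    centers <- sort(pmin(pmax(slots + jit, lo), hi))
    role <- rep("shared", n_total)
    if (n_regions > 0 && spec$n_diff > 0) {
      diff_slots <- round(seq(2, n_total - 1, length.out =
                                n_regions * spec$n_diff))
      role[diff_slots] <- rep(paste0("region", seq_len(n_regions)),
                              spec$n_diff)
    }
    intensity <- stats::rlnorm(n_total, spec$shared_intensity[1],
                               spec$shared_intensity[2])
    intensity[role != "shared"] <- spec$diff_intensity
    panel <- data.frame(mz = centers, intensity = intensity, role = role,
                        width_ppm = spec$peak_width_ppm,
                        stringsAsFactors = FALSE)
    sep_ppm <- diff(panel$mz) / panel$mz[-n_total] * 1e6
    is_diff <- panel$role != "shared"
    near_diff <- (is_diff[-n_total] | is_diff[-1])
    if (any(near_diff & sep_ppm < 2 * spec$peak_width_ppm))
      stop("differential peaks closer than 2x peak width to a neighbour; ",
           "ground truth would be ambiguous")
    panel
  })
}

phantom_masks <- function(spec) {
  nx <- spec$grid[1]; ny <- spec$grid[2]
  coords <- cbind(x = rep(0:(nx - 1L), times = ny),
                  y = rep(0:(ny - 1L), each = nx))
  region_of <- rep(0L, nrow(coords))
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    inside <- ((coords[, "x"] - r$cx) / r$rx)^2 +
      ((coords[, "y"] - r$cy) / r$ry)^2 <= 1
    if (any(region_of[inside] != 0L))
      stop("phantom regions overlap")
    region_of[inside] <- i
  }
  list(coords = coords, region_of = region_of)
}

phantom_truth <- function(spec, panel, masks, feature_space) {
  n_regions <- length(spec$regions)
  rn <- c("background",
          if (n_regions > 0) paste0("region", seq_len(n_regions)))
  profiles <- matrix(0, n_regions + 1L, nrow(panel),
                     dimnames = list(rn, NULL))
  for (i in 0:n_regions) {
    keep <- panel$role == "shared" |
      panel$role == paste0("region", i)
    profiles[i + 1L, ] <- ifelse(keep, panel$intensity, 0)
  }
  masks_list <- lapply(seq_len(n_regions), function(i)
    masks$coords[masks$region_of == i, , drop = FALSE])
  if (n_regions > 0)
    names(masks_list) <- paste0("region", seq_len(n_regions))
  structure(list(region_masks = masks_list, region_of = masks$region_of,
                 coords = masks$coords, profiles = profiles, panel = panel,
                 feature_space = feature_space),
            class = "phantom_truth")
}

#' Generate a profile-mode synthetic imaging MS dataset
#'
#' Each pixel spectrum is a sum of Gaussian peaks (the shared panel plus the
#' pixel's region-specific differential panel), an exponentially decaying
#' baseline and i.i.d. Gaussian noise clipped at zero, all multiplied by a
#' per-pixel log-normal TIC factor. Fully reproducible from the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return List with `dataset` (an `msi_dataset`) and `truth` (a
#'   `phantom_truth` holding region masks, per-region expected profiles and
#'   the planted peak panel).
#' @export
generate_profile_phantom <- function(spec) {
  panel <- phantom_panel(spec)
  masks <- phantom_masks(spec)
  mz <- seq(spec$mz_range[1], spec$mz_range[2], by = spec$mz_step)
  n_regions <- length(spec$regions)
  templates <- matrix(0, n_regions + 1L, length(mz))
  baseline <- spec$baseline_amplitude *
    exp(-(mz - mz[1]) / spec$baseline_decay)
  for (i in 0:n_regions) {
    keep <- panel$role == "shared" | panel$role == paste0("region", i)
    sub <- panel[keep, , drop = FALSE]
    s <- baseline
    for (j in seq_len(nrow(sub))) {
      sigma <- sub$mz[j] * sub$width_ppm[j] * 1e-6 / (2 * sqrt(2 * log(2)))
      s <- s + sub$intensity[j] * exp(-(mz - sub$mz[j])^2 / (2 * sigma^2))
    }
    templates[i + 1L, ] <- s
  }
  mat <- with_seed(spec$seed, {
    m <- templates[masks$region_of + 1L, , drop = FALSE]
    m <- m + matrix(stats::rnorm(length(m), sd = spec$noise_sd), nrow(m))
    m <- pmax(m, 0)
    tic <- stats::rlnorm(nrow(m), 0, spec$tic_sd)
    m * tic
  })
  dataset <- msi_dataset(masks$coords, mz, mat,
                         dataset_id = paste0("phantom", spec$seed))
  list(dataset = dataset,
       truth = phantom_truth(spec, panel, masks, feature_space = "profile"))
}

#' Generate a reduced (pixels x features) synthetic phantom
#'
#' Emits the reduced feature matrix directly, skipping the profile stage:
#' one feature per planted peak, with the same region semantics, additive
#' clipped Gaussian noise and log-normal TIC drift as
#' [generate_profile_phantom()]. This is the fast path for exercising the
#' multivariate and agreement stages.
#'
#' @param spec a [phantom_spec()].
#' @return List with `dataset` (a `reduced_dataset`, normalization `"none"`)
#'   and `truth` (a `phantom_truth`).
#' @export
generate_reduced_phantom <- function(spec) {
  panel <- phantom_panel(spec)
  masks <- phantom_masks(spec)
  truth <- phantom_truth(spec, panel, masks, feature_space = "reduced")
  profiles <- truth$profiles
  mat <- with_seed(spec$seed + 1L, {
    m <- profiles[masks$region_of + 1L, , drop = FALSE]
    m <- m + matrix(stats::rnorm(length(m), sd = spec$noise_sd), nrow(m))
    m <- pmax(m, 0)
    tic <- stats::rlnorm(nrow(m), 0, spec$tic_sd)
    m * tic
  })
  dataset <- reduced_dataset(masks$coords, panel$mz, mat,
                             feature_window_ppm = spec$peak_width_ppm,
                             dataset_id = paste0("phantom", spec$seed))
  list(dataset = dataset, truth = truth)
}
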