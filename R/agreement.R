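#' Agreement analysis configuration
#'
#' @param methods ordered methods participating in the agreement (default:
#'   the five-method set; k-means is exploratory and excluded).
#' @param top_k number of leading components per method considered for
#'   matching.
#' @param intensity_threshold_frac fraction of an image's maximum above which
#'   a pixel is set to one before summation (default 0.40: background signal
#'   sits mostly below 40% of the maximum).
#' @param cutdown_corr correlation above which a lower-ranked agreement plot
#'   is discarded as redundant (default 0.70).
#' @param thresholded whether the primary agreement image is the thresholded
#'   integer sum (the continuous variant is always computed alongside).
#' @return An `agreement_config` list.
#' @export
agreement_config <- function(methods = c("pca", "nnmf", "maf", "fcm",
                                         "plsa"),
                             top_k = 8L, intensity_threshold_frac = 0.40,
                             cutdown_corr = 0.70, thresholded = TRUE) {
  stopifnot(length(methods) >= 2,
            intensity_threshold_frac > 0, intensity_threshold_frac < 1,
            cutdown_corr > 0, top_k >= 1)
  structure(list(methods = methods, top_k = as.integer(top_k),
                 intensity_threshold_frac = intensity_threshold_frac,
                 cutdown_corr = cutdown_corr,
                 thresholded = isTRUE(thresholded)),
            class = "agreement_config")
}

#' Pearson correlation of two unfolded component images
#'
#' Component images are unfolded into one-dimensional vectors over the tissue
#' pixels (off-tissue pixels never enter, which accommodates irregularly
#' shaped tissues) and the standard Pearson correlation computed.
#'
#' @param image_a,image_b numeric vectors over the same tissue pixel set.
#' @return Pearson r; if either image has zero variance, 0 with a warning.
#' @export
unfolded_pearson <- function(image_a, image_b) {
  stopifnot(length(image_a) == length(image_b))
  if (stats::sd(image_a) == 0 || stats::sd(image_b) == 0) {
    warning("zero-variance image: correlation defined as 0")
    return(0)
  }
  stats::cor(image_a, image_b)
}

#' Match one method's components against the other methods
#'
#' Each of the template method's leading `top_k` component images is used to
#' sort the components of every other method: the candidate (among that
#' method's leading `top_k`) with the highest unfolded Pearson correlation is
#' the best match. For sign-indefinite candidates (PCA, MAF) both signs are
#' tried and the better-correlating sign recorded as a flip flag.
#' Many-to-one matching is allowed; ties break towards the lower component
#' index.
#'
#' @param template a [component_set()] acting as template.
#' @param others list of [component_set()] objects over the same pixels.
#' @param config an [agreement_config()].
#' @return A list of `match_result` objects, one per template component:
#'   each has `$template` (method, index) and `$matched`, a named list per
#'   other method with elements `index`, `r`, `flip`.
#' @export
match_components <- function(template, others, config = agreement_config()) {
  for (o in others)
    if (!identical(dim(o$scores)[1], dim(template$scores)[1]) ||
        !identical(o$coords, template$coords))
      stop("component sets are defined over differing pixel sets")
  kt <- min(config$top_k, ncol(template$scores))
  lapply(seq_len(kt), function(ti) {
    timg <- template$scores[, ti]
    matched <- lapply(others, function(o) {
      ko <- min(config$top_k, ncol(o$scores))
      rs <- vapply(seq_len(ko), function(ci)
        suppressWarnings(unfolded_pearson(timg, o$scores[, ci])),
        numeric(1))
      eff <- if (o$sign_definite) rs else abs(rs)
      best <- which.max(eff)   # which.max takes the first (lowest index) tie
      list(index = best, r = eff[best],
           flip = !o$sign_definite && rs[best] < 0)
    })
    names(matched) <- vapply(others, function(o) o$method, "")
    structure(list(template = list(method = template$method, index = ti),
                   matched = matched),
              class = "match_result")
  })
}

#' Threshold a component image at a fraction of its maximum
#'
#' Pixels with intensity strictly greater than `frac` times the image
#' maximum become one, all others zero. Expects a sign-oriented image with
#' negatives already clipped to zero.
#'
#' @param image numeric vector (unfolded image over tissue pixels).
#' @param frac threshold fraction in (0, 1).
#' @return A 0/1 numeric vector; if the maximum is not positive, all zeros
#'   with a warning.
#' @export
threshold_image <- function(image, frac = 0.40) {
  m <- max(image)
  if (m <= 0) {
    warning("image has no positive maximum; thresholded image is all zero")
    return(rep(0, length(image)))
  }
  as.numeric(image > frac * m)
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
}

oriented_image <- function(cs, index, flip) {
  img <- cs$scores[, index]
  if (flip) img <- -img
  pmax(img, 0)
}

oriented_loading <- function(cs, index, flip) {
  l <- cs$loadings[index, ]
  if (flip) l <- -l
  l
}

basepeak_norm <- function(l) {
  m <- max(l)
  if (m <= 0) m <- max(abs(l))
  if (m == 0) return(l)
  l / m
}

#' Build one agreement plot from a match result
#'
#' The template's own component image and its matched images from the other
#' methods are sign-oriented, negatives clipped to zero, thresholded at
#' `intensity_threshold_frac` of each image's maximum, and summed into an
#' integer image in `0..M` (M = number of methods): the per-pixel count of
#' methods marking that pixel. A continuous variant sums the same images
#' min-max scaled to [0, 1] without thresholding (used for correlation-based
#' comparisons, where the discrete scale would be ill-suited). The consensus
#' spectrum is the mean of the M matched loading vectors, each normalized to
#' its basepeak, renormalized to maximum 1.
#'
#' @param match a `match_result` from [match_components()].
#' @param components named list of all participating [component_set()]s
#'   (template included).
#' @param config an [agreement_config()].
#' @return An `agreement_plot`: list with `image` (integer), `continuous`,
#'   `consensus_spectrum`, `coords`, `match`, `rank_key`, `mean_r`,
#'   `n_methods`.
#' @export
build_agreement <- function(match, components, config = agreement_config()) {
  tmpl <- components[[match$template$method]]
  members <- list(list(cs = tmpl, index = match$template$index,
                       flip = FALSE))
  for (m in names(match$matched)) {
    mm <- match$matched[[m]]
    members <- c(members, list(list(cs = components[[m]], index = mm$index,
                                    flip = mm$flip)))
  }
  imgs <- lapply(members, function(x) oriented_image(x$cs, x$index, x$flip))
  thresholded <- lapply(imgs, function(im)
    suppressWarnings(threshold_image(im, config$intensity_threshold_frac)))
  image <- Reduce(`+`, thresholded)
  continuous <- Reduce(`+`, lapply(imgs, minmax01))
  loadings <- lapply(members, function(x)
    basepeak_norm(oriented_loading(x$cs, x$index, x$flip)))
  consensus <- Reduce(`+`, loadings) / length(loadings)
  cmax <- max(consensus)
  if (cmax > 0) consensus <- consensus / cmax
  rs <- vapply(match$matched, function(mm) mm$r, numeric(1))
  structure(list(image = as.integer(round(image)), continuous = continuous,
                 consensus_spectrum = consensus, coords = tmpl$coords,
                 feature_mz = tmpl$feature_mz, match = match,
                 rank_key = sum(rs >= 0.7), mean_r = mean(rs),
                 n_methods = length(members)),
            class = "agreement_plot")
}

#' @export
print.agreement_plot <- function(x, ...) {
  cat(sprintf(
    "agreement_plot [template %s #%d]: %d methods, %d/%d matches r>=0.7, mean r %.2f\n",
    x$match$template$method, x$match$template$index, x$n_methods,
    x$rank_key, length(x$match$matched), x$mean_r))
  invisible(x)
}

#' Remove redundant agreement plots
#'
#' Iterating every method as template produces many agreement plots showing
#' the same spatial variation. The cutdown first sorts the plots by the
#' number of correlated images (matches with r >= 0.7, ties broken by mean
#' match correlation), then walks down the ranking and discards any plot
#' whose continuous image correlates above `cutdown_corr` with an
#' already-kept plot.
#'
#' @param plots list of [build_agreement()] outputs.
#' @param config an [agreement_config()].
#' @return The retained plots, in rank order.
#' @export
cutdown <- function(plots, config = agreement_config()) {
  if (length(plots) == 0L) return(list())
  ord <- order(vapply(plots, `[[`, 0, "rank_key"),
               vapply(plots, `[[`, 0, "mean_r"),
               decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    p <- plots[[i]]
    redundant <- any(vapply(kept, function(q)
      suppressWarnings(unfolded_pearson(p$continuous, q$continuous)) >
        config$cutdown_corr, logical(1)))
    if (!redundant) kept[[length(kept) + 1L]] <- p
  }
  kept
}

#' Run the full agreement analysis on a project dataset
#'
#' Decomposes the reduced (TIC-normalized) project dataset with every
#' configured method, iterates each method as template over its leading
#' `top_k` components, builds the agreement plots and removes redundancy
#' with [cutdown()]. Deterministic for a fixed seed.
#'
#' @param project a TIC-normalized `reduced_dataset`.
#' @param config an [agreement_config()].
#' @param fconfig a [factorize_config()] (carries the seed and K).
#' @param components optional precomputed named list of [component_set()]s;
#'   when supplied the decomposition stage is skipped.
#' @return List with `plots` (surviving [build_agreement()] outputs),
#'   `all_plots`, `components`, and the two configs as a run record.
#' @export
run_agreement <- function(project, config = agreement_config(),
                          fconfig = factorize_config(),
                          components = NULL) {
  if (is.null(components)) {
    if (project$normalization != "tic")
      project <- tic_normalize(project)
    components <- run_methods(project, methods = config$methods,
                              config = fconfig)
  }
  # canonicalize sign-indefinite components (score skewness >= 0) so the
  # analysis is invariant to arbitrary component negation by the caller
  components <- lapply(components, function(cs) {
    if (!cs$sign_definite) {
      o <- orient_signs(cs$scores, cs$loadings)
      cs$scores <- o$scores
      cs$loadings <- o$loadings
    }
    cs
  })
  all_plots <- list()
  for (m in config$methods) {
    matches <- match_components(components[[m]],
                                components[setdiff(config$methods, m)],
                                config)
    all_plots <- c(all_plots,
                   lapply(matches, build_agreement, components = components,
                          config = config))
  }
  list(plots = cutdown(all_plots, config), all_plots = all_plots,
       components = components, config = config, fconfig = fconfig)
}

# restrict a plot's continuous image to pixels originating from the given
# source datasets (requires the project's provenance)
restrict_to_sources <- function(plot, provenance, sources) {
  sel <- provenance$source_id %in% sources
  list(values = plot$continuous[sel],
       key = paste(provenance$source_id[sel], provenance$source_x[sel],
                   provenance$source_y[sel]))
}

#' Cross-validated agreement analysis
#'
#' Randomly splits the datasets into `k` sub-groups and runs the agreement
#' analysis on each leave-one-group-out subset. Regions found in different
#' folds are compared by correlating their continuous agreement images over
#' the pixels of the datasets shared between the two folds; the best-match
#' correlation quantifies how stable each region is to the composition of
#' the series.
#'
#' @param datasets list of `reduced_dataset` objects (same feature panel).
#' @param k number of folds (>= 2, <= number of datasets).
#' @param seed integer seed for the fold assignment and the decompositions.
#' @param config an [agreement_config()].
#' @param fconfig a [factorize_config()]; its seed is overridden by `seed`.
#' @return List with `similarity` (k x k matrix: mean over fold i's plots of
#'   the best correlation to fold j's plots on shared datasets), `folds`
#'   (the assignment) and `results` (per-fold [run_agreement()] outputs).
#' @export
cross_validated_agreement <- function(datasets, k, seed = 1L,
                                      config = agreement_config(),
                                      fconfig = factorize_config()) {
  if (k < 2) stop("k must be at least 2")
  if (length(datasets) < k) stop("need at least k datasets")
  fconfig$seed <- as.integer(seed)
  folds <- with_seed(seed,
                     sample(rep_len(seq_len(k), length(datasets))))
  ids <- vapply(datasets, function(d) d$dataset_id, "")
  results <- vector("list", k)
  merged <- vector("list", k)
  for (i in seq_len(k)) {
    merged[[i]] <- tic_normalize(
      merge_datasets(datasets[folds != i],
                     dataset_id = paste0("fold", i)))
    results[[i]] <- run_agreement(merged[[i]], config, fconfig)
  }
  sim <- diag(1, k)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    shared <- ids[folds != i & folds != j]
    best <- vapply(results[[i]]$plots, function(p) {
      a <- restrict_to_sources(p, merged[[i]]$provenance, shared)
      max(vapply(results[[j]]$plots, function(q) {
        b <- restrict_to_sources(q, merged[[j]]$provenance, shared)
        idx <- match(a$key, b$key)
        suppressWarnings(unfolded_pearson(a$values[!is.na(idx)],
                                          b$values[idx[!is.na(idx)]]))
      }, numeric(1)))
    }, numeric(1))
    sim[i, j] <- sim[j, i] <- mean(best)
  }
  list(similarity = sim, folds = folds, results = results)
}
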