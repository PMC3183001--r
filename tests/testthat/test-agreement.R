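test_that("unfolded Pearson matches the direct formula", {
  expect_equal(unfolded_pearson(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(unfolded_pearson(c(1, 2, 3), -c(1, 2, 3)), -1.0)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unfolded_pearson(x, y), direct)
  expect_equal(round(direct, 5), 0.98198)
  expect_warning(r0 <- unfolded_pearson(c(1, 1, 1), c(1, 2, 3)),
                 "zero-variance")
  expect_identical(r0, 0)
})

test_that("threshold rule is a strict >40%-of-max comparison", {
  expect_equal(threshold_image(c(0, 2, 5, 10), 0.4), c(0, 0, 1, 1))
  expect_equal(threshold_image(rep(3, 5), 0.4), rep(1, 5))
  expect_warning(z <- threshold_image(rep(0, 4), 0.4), "no positive")
  expect_equal(z, rep(0, 4))
  # oracle: elementwise comparison on random images
  set.seed(3)
  for (i in 1:10) {
    img <- runif(50, 0, 7)
    expect_equal(threshold_image(img, 0.4),
                 as.numeric(img > 0.4 * max(img)))
  }
})

make_cs <- function(method, scores, coords, fmz = NULL) {
  if (is.null(fmz)) fmz <- seq(3000, 3000 + 100 * (ncol(scores) - 1), 100)
  loadings <- matrix(abs(sin(seq_len(ncol(scores) * length(fmz)))) + 0.1,
                     ncol(scores), length(fmz))
  if (method == "plsa") loadings <- loadings / rowSums(loadings)
  component_set(method, scores, loadings, coords, fmz)
}

test_that("matching recovers identity, permutations, and sign flips", {
  set.seed(6)
  n <- 40
  coords <- cbind(x = rep(0:7, 5), y = rep(0:4, each = 8))
  S <- matrix(runif(n * 4), n, 4)
  tmpl <- make_cs("nnmf", S, coords)
  cfg <- agreement_config(top_k = 4)

  # identity: every component matches itself at r = 1
  ident <- match_components(tmpl, list(make_cs("plsa",
    sweep(S, 2, colSums(S), "/"), coords)), cfg)
  for (k in 1:4) {
    expect_identical(ident[[k]]$matched$plsa$index, k)
    expect_equal(ident[[k]]$matched$plsa$r, 1, tolerance = 1e-9)
  }
  # permutation recovered
  perm <- c(3, 1, 4, 2)
  pm <- match_components(tmpl, list(make_cs("nnmf", S[, perm], coords)),
                         cfg)
  for (k in 1:4)
    expect_identical(pm[[k]]$matched$nnmf$index, match(k, perm))
  # negated sign-indefinite components matched with the flip flag
  fm <- match_components(tmpl, list(make_cs("pca", -S, coords)), cfg)
  for (k in 1:4) {
    expect_identical(fm[[k]]$matched$pca$index, k)
    expect_true(fm[[k]]$matched$pca$flip)
    expect_equal(fm[[k]]$matched$pca$r, 1, tolerance = 1e-9)
  }
  expect_error(match_components(tmpl,
    list(make_cs("pca", S[-1, ], coords[-1, ]))), "pixel")
})

test_that("agreement summation equals the per-pixel brute-force sum", {
  set.seed(9)
  n <- 60
  coords <- cbind(x = rep(0:9, 6), y = rep(0:5, each = 10))
  sets <- list()
  for (m in c("nnmf", "fcm", "plsa")) {
    S <- matrix(runif(n * 2, 0, 5), n, 2)
    if (m == "fcm") S <- S / rowSums(S)
    if (m == "plsa") S <- sweep(S, 2, colSums(S), "/")
    sets[[m]] <- make_cs(m, S, coords)
  }
  cfg <- agreement_config(methods = names(sets), top_k = 2)
  match <- match_components(sets$nnmf, sets[c("fcm", "plsa")], cfg)[[1]]
  plot <- build_agreement(match, sets, cfg)
  # brute force: threshold each member image independently and add
  member_imgs <- list(sets$nnmf$scores[, 1],
                      sets$fcm$scores[, match$matched$fcm$index],
                      sets$plsa$scores[, match$matched$plsa$index])
  brute <- Reduce(`+`, lapply(member_imgs, function(v)
    as.numeric(v > 0.4 * max(v))))
  expect_equal(as.numeric(plot$image), brute)
  expect_true(all(plot$image >= 0 & plot$image <= 3))
  expect_equal(max(plot$consensus_spectrum), 1)
})

test_that("identical and disjoint binary stacks sum as expected", {
  n <- 30
  coords <- cbind(x = rep(0:5, 5), y = rep(0:4, each = 6))
  mask <- as.numeric(seq_len(n) <= 10)
  sets <- list()
  meths <- c("nnmf", "fcm", "plsa", "kmeans", "maf")
  for (i in seq_along(meths)) {
    m <- meths[i]
    S <- cbind(mask, 1 - mask) + 1e-9
    if (m == "fcm") S <- S / rowSums(S)
    if (m == "plsa") S <- sweep(S, 2, colSums(S), "/")
    if (m == "kmeans") S <- round(S)
    sets[[m]] <- make_cs(m, S, coords)
  }
  cfg <- agreement_config(methods = meths, top_k = 1)
  match <- match_components(sets$nnmf, sets[meths[-1]], cfg)[[1]]
  plot <- build_agreement(match, sets, cfg)
  expect_equal(as.numeric(plot$image), 5 * mask)
})

test_that("cutdown keeps the highest-ranked representative of each family", {
  n <- 50
  coords <- cbind(x = rep(0:9, 5), y = rep(0:4, each = 10))
  set.seed(2)
  base <- runif(n)
  mk_plot <- function(img, rank_key, mean_r) {
    structure(list(image = as.integer(img > 0.5), continuous = img,
                   consensus_spectrum = rep(1, 3), coords = coords,
                   feature_mz = c(3e3, 4e3, 5e3),
                   match = list(template = list(method = "nnmf", index = 1),
                                matched = list()),
                   rank_key = rank_key, mean_r = mean_r, n_methods = 5),
              class = "agreement_plot")
  }
  A <- mk_plot(base, 5, 0.95)
  B <- mk_plot(base + rnorm(n, sd = 0.05), 4, 0.90)       # r ~ 0.95 with A
  C <- mk_plot(runif(n), 3, 0.85)                          # independent
  expect_gt(unfolded_pearson(A$continuous, B$continuous), 0.9)
  kept <- cutdown(list(C, B, A), agreement_config())
  expect_identical(length(kept), 2L)
  expect_identical(kept[[1]]$rank_key, 5)
  expect_identical(kept[[2]]$rank_key, 3)
  # identical plots collapse to one; mutually uncorrelated ones all survive
  expect_identical(length(cutdown(list(A, A), agreement_config())), 1L)
  expect_identical(length(cutdown(list(A, C), agreement_config())), 2L)
  expect_identical(cutdown(list(), agreement_config()), list())
})

test_that("cutdown agrees with an exhaustive greedy oracle on small sets", {
  set.seed(33)
  n <- 40
  coords <- cbind(x = rep(0:7, 5), y = rep(0:4, each = 8))
  for (trial in 1:5) {
    plots <- lapply(1:6, function(i) {
      structure(list(image = integer(n), continuous = runif(n),
                     consensus_spectrum = 1, coords = coords,
                     feature_mz = 3e3,
                     match = list(template = list(method = "nnmf",
                                                  index = i),
                                  matched = list()),
                     rank_key = sample(0:4, 1), mean_r = runif(1),
                     n_methods = 5), class = "agreement_plot")
    })
    kept <- cutdown(plots, agreement_config())
    # oracle: explicit greedy walk in rank order
    ord <- order(sapply(plots, `[[`, "rank_key"),
                 sapply(plots, `[[`, "mean_r"), decreasing = TRUE)
    oracle <- list()
    for (i in ord) {
      ok <- all(vapply(oracle, function(q)
        cor(plots[[i]]$continuous, q$continuous) <= 0.7, logical(1)))
      if (ok) oracle[[length(oracle) + 1]] <- plots[[i]]
    }
    expect_identical(sapply(kept, function(p) p$match$template$index),
                     sapply(oracle, function(p) p$match$template$index))
  }
})

test_that("negating a sign-indefinite component leaves surviving plots unchanged", {
  gp <- generate_reduced_phantom(small_phantom_spec(seed = 55))
  proj <- tic_normalize(gp$dataset)
  fcfg <- factorize_config(n_components = 3, seed = 5)
  acfg <- agreement_config(top_k = 3)
  sets <- suppressWarnings(run_methods(proj, config = fcfg))
  res1 <- run_agreement(proj, acfg, fcfg, components = sets)
  sets2 <- sets
  sets2$pca$scores[, 2] <- -sets2$pca$scores[, 2]
  sets2$pca$loadings[2, ] <- -sets2$pca$loadings[2, ]
  sets2$maf$scores[, 1] <- -sets2$maf$scores[, 1]
  sets2$maf$loadings[1, ] <- -sets2$maf$loadings[1, ]
  res2 <- run_agreement(proj, acfg, fcfg, components = sets2)
  expect_identical(length(res1$plots), length(res2$plots))
  for (i in seq_along(res1$plots))
    expect_equal(res1$plots[[i]]$image, res2$plots[[i]]$image)
})

test_that("raising the threshold fraction never increases agreement values", {
  gp <- generate_reduced_phantom(small_phantom_spec(seed = 66))
  proj <- tic_normalize(gp$dataset)
  fcfg <- factorize_config(n_components = 3, seed = 6)
  sets <- suppressWarnings(run_methods(proj, config = fcfg))
  lo <- agreement_config(top_k = 3, intensity_threshold_frac = 0.3)
  hi <- agreement_config(top_k = 3, intensity_threshold_frac = 0.6)
  m <- match_components(sets$nnmf, sets[c("pca", "maf", "fcm", "plsa")],
                        lo)[[1]]
  p_lo <- build_agreement(m, sets, lo)
  p_hi <- build_agreement(m, sets, hi)
  expect_true(all(p_hi$image <= p_lo$image))
})

test_that("template iteration is exhaustive so method order does not matter", {
  gp <- generate_reduced_phantom(small_phantom_spec(seed = 77))
  proj <- tic_normalize(gp$dataset)
  fcfg <- factorize_config(n_components = 2, seed = 7)
  a <- suppressWarnings(run_agreement(proj,
         agreement_config(methods = c("pca", "nnmf", "maf", "fcm", "plsa"),
                          top_k = 2), fcfg))
  b <- suppressWarnings(run_agreement(proj,
         agreement_config(methods = c("plsa", "fcm", "maf", "nnmf", "pca"),
                          top_k = 2), fcfg))
  key <- function(res) sort(vapply(res$plots, function(p)
    paste(p$match$template$method, p$match$template$index), ""))
  expect_identical(key(a), key(b))
})

test_that("spectrally identical regions are not separated (negative control)", {
  # two regions whose differential panels are forced to be identical
  spec <- phantom_spec(grid = c(24L, 20L),
                       regions = list(list(cx = 6, cy = 6, rx = 4, ry = 3),
                                      list(cx = 17, cy = 13, rx = 4, ry = 4)),
                       n_shared = 30L, n_diff = 3L, seed = 88)
  gp <- generate_reduced_phantom(spec)
  panel <- gp$truth$panel
  # overwrite: give region2 the same profile as region1
  prof <- gp$truth$profiles
  prof["region2", ] <- prof["region1", ]
  m <- msiagree:::with_seed(1, {
    mm <- prof[gp$truth$region_of + 1, ]
    mm + matrix(rnorm(length(mm), sd = 2.5), nrow(mm))
  })
  rd <- reduced_dataset(gp$truth$coords, panel$mz, pmax(m, 0))
  res <- suppressWarnings(run_agreement(tic_normalize(rd),
    agreement_config(top_k = 3), factorize_config(n_components = 3,
                                                  seed = 8)))
  r1 <- gp$truth$region_of == 1
  r2 <- gp$truth$region_of == 2
  isolates <- vapply(res$plots, function(p) {
    hit <- p$image >= 4
    (jaccard(hit, r1) > 0.5 && jaccard(hit, r2) < 0.1) ||
      (jaccard(hit, r2) > 0.5 && jaccard(hit, r1) < 0.1)
  }, logical(1))
  expect_false(any(isolates))
})

test_that("cross-validated agreement is stable across folds of replicates", {
  datasets <- lapply(1:4, function(i) {
    spec <- phantom_spec(grid = c(20L, 16L),
                         regions = list(list(cx = 9, cy = 7, rx = 5,
                                             ry = 4)),
                         n_shared = 25L, n_diff = 4L, seed = 99)
    gp <- generate_reduced_phantom(spec)
    d <- gp$dataset
    d$dataset_id <- paste0("pat", i)
    d$provenance$source_id <- paste0("pat", i)
    d
  })
  cv <- suppressWarnings(cross_validated_agreement(
    datasets, k = 4, seed = 3,
    config = agreement_config(top_k = 2),
    fconfig = factorize_config(n_components = 2)))
  expect_identical(dim(cv$similarity), c(4L, 4L))
  off <- cv$similarity[upper.tri(cv$similarity)]
  expect_true(all(off > 0.9))
  cv2 <- suppressWarnings(cross_validated_agreement(
    datasets, k = 4, seed = 3,
    config = agreement_config(top_k = 2),
    fconfig = factorize_config(n_components = 2)))
  expect_identical(cv$folds, cv2$folds)
  expect_error(cross_validated_agreement(datasets, k = 1), "at least 2")
})
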