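test_that("PCA recovers axis-aligned variance and conserves total variance", {
  set.seed(4)
  n <- 50
  coords <- cbind(x = rep(0:9, 5), y = rep(0:4, each = 10))
  # variance along feature 1 only
  m <- cbind(runif(n, 0, 10), matrix(5, n, 3)) + 100
  rd <- reduced_dataset(coords, c(3e3, 4e3, 5e3, 6e3), m)
  cs <- suppressWarnings(run_pca(rd, factorize_config(n_components = 2)))
  expect_gt(abs(cs$loadings[1, 1]), 0.999)

  m2 <- matrix(runif(n * 10), n, 10)
  rd2 <- reduced_dataset(coords, seq(3e3, 3e3 + 9 * 100, 100), m2)
  cs2 <- run_pca(rd2, factorize_config(n_components = 10))
  expect_equal(sum(cs2$diagnostics$explained_variance),
               cs2$diagnostics$total_variance, tolerance = 1e-8)
  # completeness: full reconstruction equals the centered matrix
  centered <- scale(m2, center = TRUE, scale = FALSE)
  expect_equal(cs2$scores %*% cs2$loadings, unclass(centered),
               tolerance = 1e-8, ignore_attr = TRUE)
  # orthonormal loadings
  expect_equal(cs2$loadings %*% t(cs2$loadings), diag(10), tolerance = 1e-8)
})

test_that("NNMF reconstructs a rank-1 matrix to the singular-pair optimum", {
  set.seed(8)
  n <- 30; f <- 6
  coords <- cbind(x = rep(0:5, 5), y = rep(0:4, each = 6))
  w <- runif(n, 1, 2); h <- runif(f, 1, 3)
  X <- outer(w, h)
  rd <- reduced_dataset(coords, seq(3e3, 3e3 + (f - 1) * 100, 100), X)
  cs <- run_nnmf(rd, factorize_config(n_components = 1, seed = 2))
  rel <- sqrt(sum((X - cs$scores %*% cs$loadings)^2) / sum(X^2))
  expect_lt(rel, 1e-3)
  expect_true(all(cs$scores >= 0) && all(cs$loadings >= 0))
})

test_that("NNMF objective is non-increasing for several seeds", {
  rd <- tiny_reduced(n = 20, f = 5, seed = 6)
  for (s in 1:3) {
    cs <- run_nnmf(rd, factorize_config(n_components = 3, seed = s,
                                        nnmf_restarts = 1))
    obj <- cs$diagnostics$objective
    expect_true(all(diff(obj) <= 1e-10 * pmax(obj[-length(obj)], 1)))
  }
  expect_error(run_nnmf(reduced_dataset(cbind(x = 0:1, y = c(0L, 0L)),
                                        c(5e3, 6e3),
                                        matrix(c(-1, 1, 1, 1), 2, 2))),
               "non-negative")
})

test_that("NNMF separates a two-region phantom", {
  bl <- blob_reduced(seed = 3)
  cs <- run_nnmf(bl$data, factorize_config(n_components = 2, seed = 1))
  r1 <- max(abs(cor(cs$scores[, 1], bl$truth)),
            abs(cor(cs$scores[, 2], bl$truth)))
  expect_gt(r1, 0.9)
})

test_that("MAF puts the spatial gradient first and noise last", {
  set.seed(10)
  nx <- 20; ny <- 10
  coords <- cbind(x = rep(0:(nx - 1), ny), y = rep(0:(ny - 1), each = nx))
  grad <- coords[, "x"] / nx
  m <- cbind(grad + rnorm(nx * ny, sd = 0.01), rnorm(nx * ny, sd = 1) + 5)
  m <- m - min(m)
  rd <- reduced_dataset(coords, c(5e3, 6e3), m)
  cs <- run_maf(rd, factorize_config(n_components = 2))
  l1 <- cs$loadings[1, ]
  expect_gt(abs(l1[1]) / sqrt(sum(l1^2)), 0.95)
  # ordering: MAF1 has the highest lag-1 spatial autocorrelation
  moran <- function(v) {
    key <- paste(coords[, 1], coords[, 2])
    j <- match(paste(coords[, 1] + 1, coords[, 2]), key)
    ok <- !is.na(j)
    cor(v[ok], v[j[ok]])
  }
  expect_gte(moran(cs$scores[, 1]) + 1e-9, moran(cs$scores[, 2]))
})

test_that("permuting pixel positions destroys the MAF ordering signal", {
  set.seed(11)
  nx <- 16; ny <- 10
  coords <- cbind(x = rep(0:(nx - 1), ny), y = rep(0:(ny - 1), each = nx))
  m <- cbind(coords[, "x"] / nx + rnorm(nx * ny, sd = 0.01),
             rnorm(nx * ny, sd = 1) + 5)
  m <- m - min(m)
  rd <- reduced_dataset(coords, c(5e3, 6e3), m)
  ac_true <- run_maf(rd, factorize_config(n_components = 2))$
    diagnostics$autocorrelation[1]
  perm <- sample(nrow(coords))
  rd_shuf <- reduced_dataset(coords, c(5e3, 6e3), m[perm, ])
  ac_shuf <- run_maf(rd_shuf, factorize_config(n_components = 2))$
    diagnostics$autocorrelation[1]
  expect_gt(ac_true, 0.9)
  expect_lt(ac_shuf, 0.5)
})

test_that("MAF excludes pixel pairs that span a merge gutter", {
  # two tissues with opposite gradients; pairing across the gutter would
  # create a huge artificial difference at the seam
  mk <- function(id, flip) {
    nx <- 8; ny <- 8
    coords <- cbind(x = rep(0:(nx - 1), ny), y = rep(0:(ny - 1), each = nx))
    g <- coords[, "x"] / nx
    if (flip) g <- 1 - g
    reduced_dataset(coords, c(5e3, 6e3),
                    cbind(g, 0.5) + matrix(rnorm(2 * nx * ny, sd = 0.01),
                                           ncol = 2) + 2,
                    dataset_id = id)
  }
  set.seed(12)
  merged <- merge_datasets(list(mk("a", FALSE), mk("b", TRUE)), gutter = 1L)
  pairs <- msiagree:::shift_differences(merged)
  src <- merged$provenance$source_id
  expect_true(all(src[pairs[, 1]] == src[pairs[, 2]]))
})

test_that("k-means separates two blobs perfectly and 1 class is the mean", {
  bl <- blob_reduced(seed = 5)
  cs <- run_kmeans(bl$data, factorize_config(seed = 3), n_classes = 2)
  lab <- max.col(cs$scores)
  agree <- max(mean((lab == 1) == bl$truth), mean((lab == 2) == bl$truth))
  expect_equal(agree, 1.0)
  cs1 <- run_kmeans(bl$data, factorize_config(seed = 3), n_classes = 1)
  centered <- scale(bl$data$matrix, center = TRUE, scale = FALSE)
  expect_equal(as.numeric(cs1$loadings), rep(0, 6), tolerance = 1e-9)
  expect_error(run_kmeans(bl$data, factorize_config(), n_classes = 1000),
               "classes")
})

test_that("fuzzy memberships sum to one and harden to the k-means labels", {
  bl <- blob_reduced(seed = 9)
  cs <- run_fcm(bl$data, factorize_config(seed = 2), n_classes = 2)
  expect_equal(rowSums(cs$scores), rep(1, nrow(cs$scores)),
               tolerance = 1e-9)
  km <- run_kmeans(bl$data, factorize_config(seed = 2), n_classes = 2)
  hard <- max.col(cs$scores)
  klab <- max.col(km$scores)
  agree <- max(mean(hard == klab), mean(hard == 3 - klab))
  expect_equal(agree, 1.0)
  # near-centroid pixels take near-unit membership with m = 1.25
  expect_gt(max(cs$scores), 0.999)
})

test_that("PLSA log-likelihood is monotone and K=1 has the closed form", {
  rd <- tiny_reduced(n = 15, f = 5, seed = 13)
  cs <- run_plsa(rd, factorize_config(n_components = 3, seed = 1))
  ll <- cs$diagnostics$loglik
  expect_true(all(diff(ll) >= -1e-10 * abs(ll[-length(ll)])))
  cs1 <- run_plsa(rd, factorize_config(n_components = 1, seed = 1))
  expect_equal(as.numeric(cs1$loadings),
               colSums(rd$matrix) / sum(rd$matrix), tolerance = 1e-9)
  expect_equal(sum(cs1$scores), 1, tolerance = 1e-9)
})

test_that("PLSA recovers block-diagonal topics", {
  n <- 40; f <- 8
  coords <- cbind(x = rep(0:7, 5), y = rep(0:4, each = 8))
  set.seed(14)
  X <- matrix(0, n, f)
  X[1:20, 1:4] <- runif(80, 5, 10)
  X[21:40, 5:8] <- runif(80, 5, 10)
  rd <- reduced_dataset(coords, seq(3e3, 3e3 + 700, 100), X)
  cs <- run_plsa(rd, factorize_config(n_components = 2, seed = 3))
  mass1 <- rowSums(cs$loadings[, 1:4])
  expect_true((mass1[1] > 0.95 && mass1[2] < 0.05) ||
                (mass1[2] > 0.95 && mass1[1] < 0.05))
})

test_that("stochastic methods are bit-identical under a fixed seed", {
  bl <- blob_reduced(seed = 20)
  cfg <- factorize_config(n_components = 3, seed = 17)
  for (fn in list(run_nnmf, run_kmeans, run_fcm, run_plsa)) {
    a <- fn(bl$data, cfg)
    b <- fn(bl$data, cfg)
    expect_identical(a$scores, b$scores)
    expect_identical(a$loadings, b$loadings)
  }
})

test_that("component sets satisfy their type invariants on random phantoms", {
  for (s in 1:3) {
    gp <- generate_reduced_phantom(small_phantom_spec(seed = 400 + s))
    proj <- tic_normalize(gp$dataset)
    cfg <- factorize_config(n_components = 4, seed = s)
    sets <- suppressWarnings(
      run_methods(proj, methods = c("pca", "nnmf", "maf", "kmeans", "fcm",
                                    "plsa"), config = cfg))
    for (cs in sets) expect_s3_class(validate_component_set(cs),
                                     "component_set")
  }
})
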