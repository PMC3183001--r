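#' Factorization configuration
#'
#' Settings shared by all decompositions. Mean-centering is applied for PCA,
#' MAF, k-means and fuzzy c-means and skipped for NNMF and PLSA, which
#' require non-negative input. Defaults: 8 components, 100 NNMF iterations
#' (extended until the objective's relative change drops below 1e-6 if not
#' converged), PLSA stopped at a relative log-likelihood change below 1e-5 or
#' 500 iterations, fuzzy c-means fuzziness 1.25.
#'
#' @param n_components number of components K.
#' @param nnmf_iterations base number of multiplicative-update iterations.
#' @param nnmf_restarts random restarts for NNMF (best objective kept).
#' @param plsa_max_iterations,plsa_rel_tol PLSA EM stopping rule.
#' @param fcm_fuzziness fuzzy c-means exponent m (> 1).
#' @param fcm_tol,fcm_max_iterations fuzzy c-means stopping rule.
#' @param kmeans_restarts restarts for k-means (best within-class SSE kept).
#' @param seed integer seed driving every stochastic method.
#' @return A `factorize_config` list.
#' @export
factorize_config <- function(n_components = 8L, nnmf_iterations = 100L,
                             nnmf_restarts = 3L,
                             plsa_max_iterations = 500L, plsa_rel_tol = 1e-5,
                             fcm_fuzziness = 1.25, fcm_tol = 1e-6,
                             fcm_max_iterations = 300L,
                             kmeans_restarts = 10L, seed = 1L) {
  stopifnot(n_components >= 1, fcm_fuzziness > 1, plsa_rel_tol > 0,
            fcm_tol > 0)
  structure(list(n_components = as.integer(n_components),
                 nnmf_iterations = as.integer(nnmf_iterations),
                 nnmf_restarts = as.integer(nnmf_restarts),
                 plsa_max_iterations = as.integer(plsa_max_iterations),
                 plsa_rel_tol = plsa_rel_tol,
                 fcm_fuzziness = fcm_fuzziness, fcm_tol = fcm_tol,
                 fcm_max_iterations = as.integer(fcm_max_iterations),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 seed = as.integer(seed)),
            class = "factorize_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a component set
#'
#' The unified output of every decomposition: `scores` holds the component
#' images (pixels x K, rendered on the grid via the stored coordinates) and
#' `loadings` the component spectra (K x features).
#'
#' @param method one of `"pca"`, `"nnmf"`, `"maf"`, `"kmeans"`, `"fcm"`,
#'   `"plsa"`.
#' @param scores pixels x K score matrix.
#' @param loadings K x F loading matrix.
#' @param coords pixel coordinates matching `scores` rows.
#' @param feature_mz feature centre masses matching `loadings` columns.
#' @param diagnostics list of per-method diagnostics (objective traces etc.).
#' @return A `component_set`.
#' @export
component_set <- function(method, scores, loadings, coords, feature_mz,
                          diagnostics = list()) {
  method <- match.arg(method, c("pca", "nnmf", "maf", "kmeans", "fcm",
                                "plsa"))
  scores <- as.matrix(scores); loadings <- as.matrix(loadings)
  obj <- structure(
    list(method = method, scores = scores, loadings = loadings,
         coords = as_coords(coords), feature_mz = as.numeric(feature_mz),
         sign_definite = !(method %in% c("pca", "maf")),
         diagnostics = diagnostics),
    class = "component_set")
  validate_component_set(obj)
}

validate_component_set <- function(x) {
  stopifnot(inherits(x, "component_set"))
  if (ncol(x$scores) != nrow(x$loadings))
    stop("scores and loadings disagree on K")
  if (nrow(x$scores) != nrow(x$coords))
    stop("scores must have one row per pixel")
  if (ncol(x$loadings) != length(x$feature_mz))
    stop("loadings must have one column per feature")
  if (x$sign_definite && min(x$scores) < -1e-9)
    stop(x$method, " scores must be non-negative")
  if (x$method == "fcm") {
    rs <- rowSums(x$scores)
    if (any(abs(rs - 1) > 1e-9))
      stop("fcm memberships must sum to 1 per pixel")
  }
  if (x$method == "plsa") {
    if (any(abs(colSums(x$scores) - 1) > 1e-9) ||
        any(abs(rowSums(x$loadings) - 1) > 1e-9))
      stop("plsa probability blocks must each sum to 1")
  }
  x
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set [%s]: %d pixels x %d components, %d features\n",
              x$method, nrow(x$scores), ncol(x$scores), ncol(x$loadings)))
  invisible(x)
}

# orient sign-indefinite components so each score image has skewness >= 0
orient_signs <- function(scores, loadings) {
  for (k in seq_len(ncol(scores))) {
    s <- scores[, k]
    sk <- mean((s - mean(s))^3)
    if (sk < 0) {
      scores[, k] <- -scores[, k]
      loadings[k, ] <- -loadings[k, ]
    }
  }
  list(scores = scores, loadings = loadings)
}

center_matrix <- function(data) {
  scale(data$matrix, center = TRUE, scale = FALSE)
}

#' Principal component analysis of a reduced dataset
#'
#' Mean-centers the pixels x features matrix and computes the singular value
#' decomposition; components are ordered by descending explained variance and
#' the loading rows are orthonormal. Components are stored with the sign that
#' makes each score image's skewness non-negative.
#'
#' @param data a `reduced_dataset` (TIC-normalized in the canonical
#'   pipeline).
#' @param config a [factorize_config()].
#' @return A [component_set()]; `diagnostics$explained_variance` holds the
#'   per-component variances.
#' @export
run_pca <- function(data, config = factorize_config()) {
  X <- center_matrix(data)
  K <- config$n_components
  sv <- svd(X)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (K > rank) {
    warning("K = ", K, " exceeds matrix rank ", rank, "; truncating")
    K <- rank
  }
  scores <- sv$u[, seq_len(K), drop = FALSE] %*%
    diag(sv$d[seq_len(K)], K, K)
  loadings <- t(sv$v[, seq_len(K), drop = FALSE])
  o <- orient_signs(scores, loadings)
  component_set("pca", o$scores, o$loadings, data$coords, data$features$mz,
                diagnostics = list(
                  explained_variance = sv$d[seq_len(K)]^2 / (nrow(X) - 1),
                  total_variance = sum(sv$d^2) / (nrow(X) - 1)))
}

nnmf_fit <- function(X, K, n_iter, extend_tol = 1e-6, max_extra = 1000L) {
  n <- nrow(X); F <- ncol(X)
  eps <- 1e-12
  W <- matrix(stats::runif(n * K), n, K) * sqrt(mean(X) / K)
  H <- matrix(stats::runif(K * F), K, F) * sqrt(mean(X) / K)
  obj <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    obj[it] <- sum((X - W %*% H)^2)
    if (it >= n_iter) {
      rel <- abs(obj[it] - obj[it - 1L]) / max(obj[it - 1L], eps)
      if (rel < extend_tol || it >= n_iter + max_extra) break
    }
  }
  list(W = W, H = H, objective = obj)
}

#' Non-negative matrix factorization (multiplicative updates)
#'
#' Lee-Seung multiplicative updates minimizing the squared Frobenius
#' reconstruction error, on the raw (uncentered) non-negative matrix. Runs
#' `nnmf_iterations` iterations, extending until the relative objective
#' change falls below 1e-6 when not yet converged; the best of
#' `nnmf_restarts` random restarts is kept. Components are ordered by
#' descending contribution norm.
#'
#' @inheritParams run_pca
#' @return A [component_set()]; `diagnostics$objective` is the per-iteration
#'   reconstruction error of the winning restart.
#' @export
run_nnmf <- function(data, config = factorize_config()) {
  X <- data$matrix
  if (min(X) < 0) stop("NNMF requires non-negative input")
  K <- config$n_components
  best <- NULL
  for (r in seq_len(config$nnmf_restarts)) {
    fit <- with_seed(config$seed + 1000L * r,
                     nnmf_fit(X, K, config$nnmf_iterations))
    if (is.null(best) || utils::tail(fit$objective, 1) <
        utils::tail(best$objective, 1)) best <- fit
  }
  contrib <- sqrt(colSums(best$W^2) * rowSums(best$H^2))
  ord <- order(contrib, decreasing = TRUE)
  component_set("nnmf", pmax(best$W[, ord, drop = FALSE], 0),
                pmax(best$H[ord, , drop = FALSE], 0),
                data$coords, data$features$mz,
                diagnostics = list(objective = best$objective))
}

# one-pixel difference vectors (horizontal and vertical), never pairing
# pixels from different source datasets (merge gutters / tissue boundaries)
shift_differences <- function(data) {
  coords <- data$coords
  src <- data$provenance$source_id
  key <- paste(coords[, "x"], coords[, "y"])
  idx_of <- function(x, y) match(paste(x, y), key)
  pairs <- list()
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    j <- idx_of(coords[, "x"] + d[1], coords[, "y"] + d[2])
    ok <- !is.na(j) & src == src[ifelse(is.na(j), 1L, j)]
    pairs[[length(pairs) + 1L]] <- cbind(which(ok), j[ok])
  }
  do.call(rbind, pairs)
}

#' Maximum autocorrelation factorization
#'
#' PCA-like decomposition performed on the shift matrix: the data minus a
#' copy of itself shifted by one pixel (one horizontal and one vertical
#' shift, pooled, no additional scaling). Solving the generalized eigenproblem
#' of the difference covariance against the data covariance orders components
#' by spatial autocorrelation, so the leading factors capture spatially
#' coherent tissue structure rather than pixel noise. Pixel pairs spanning a
#' dataset boundary or merge gutter are excluded from the shift matrix.
#'
#' @inheritParams run_pca
#' @return A [component_set()]; `diagnostics$lambda` holds the generalized
#'   eigenvalues (ascending) and `diagnostics$autocorrelation` the implied
#'   lag-1 autocorrelations `1 - lambda/2`.
#' @export
run_maf <- function(data, config = factorize_config()) {
  X <- center_matrix(data)
  F <- ncol(X)
  pairs <- shift_differences(data)
  if (nrow(pairs) < F)
    warning("fewer shift pairs than features; MAF covariance is rank ",
            "deficient")
  D <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
  sigma_d <- stats::cov(D)
  sigma <- stats::cov(X)
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) {
    warning("data covariance singular; applying ridge regularization")
    sigma <- sigma + diag(1e-9 * sum(diag(sigma)) / F, F)
    R <- chol(sigma)
  }
  Ri <- backsolve(R, diag(F))
  A <- crossprod(Ri, sigma_d %*% Ri)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)   # eigenvalues descending
  K <- min(config$n_components, F)
  sel <- rev(seq_len(F))[seq_len(K)]   # ascending lambda
  W <- Ri %*% e$vectors[, sel, drop = FALSE]
  scores <- X %*% W
  loadings <- t(W)
  o <- orient_signs(scores, loadings)
  component_set("maf", o$scores, o$loadings, data$coords, data$features$mz,
                diagnostics = list(lambda = e$values[sel],
                                   autocorrelation = 1 - e$values[sel] / 2))
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1, ] <- X[i, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1L, prob = p)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering of a reduced dataset
#'
#' Hard partition of the mean-centered pixels by squared Euclidean distance,
#' with k-means++ seeding and `kmeans_restarts` restarts (best within-class
#' sum of squares kept). Scores are one-hot class indicators; loadings are
#' the class centroid spectra. Provided as an exploratory sixth method; it is
#' not part of the default agreement set.
#'
#' @inheritParams run_pca
#' @param n_classes number of classes (defaults to `config$n_components`).
#' @return A [component_set()]; `diagnostics$tot_withinss` is the winning
#'   within-class SSE.
#' @export
run_kmeans <- function(data, config = factorize_config(),
                       n_classes = config$n_components) {
  X <- center_matrix(data)
  if (n_classes > nrow(X)) stop("more classes than pixels")
  best <- NULL
  for (r in seq_len(config$kmeans_restarts)) {
    fit <- with_seed(config$seed + 1000L * r, {
      ctr <- kmeanspp_centers(X, n_classes)
      ctr <- ctr + 1e-10 * matrix(stats::rnorm(length(ctr)), nrow(ctr))
      stats::kmeans(X, centers = ctr, iter.max = 100L)
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  ord <- order(tabulate(best$cluster, n_classes), decreasing = TRUE)
  relabel <- match(seq_len(n_classes), ord)
  cl <- relabel[best$cluster]
  scores <- matrix(0, nrow(X), n_classes)
  scores[cbind(seq_len(nrow(X)), cl)] <- 1
  component_set("kmeans", scores, best$centers[ord, , drop = FALSE],
                data$coords, data$features$mz,
                diagnostics = list(tot_withinss = best$tot.withinss))
}

fcm_fit <- function(X, C, m, tol, max_iter) {
  n <- nrow(X)
  V <- X[sample.int(n, C), , drop = FALSE]
  if (anyDuplicated(V)) stop("coincident centroids")
  U <- matrix(1 / C, n, C)
  expo <- 2 / (m - 1)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(X^2), rep(1, C)) - 2 * X %*% t(V) +
      outer(rep(1, n), rowSums(V^2))
    d2 <- pmax(d2, 0)
    U_new <- matrix(0, n, C)
    zero <- d2 < 1e-300
    has_zero <- rowSums(zero) > 0
    if (any(!has_zero)) {
      inv <- d2[!has_zero, , drop = FALSE]^(-expo / 2)
      U_new[!has_zero, ] <- inv / rowSums(inv)
    }
    if (any(has_zero))
      U_new[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    delta <- max(abs(U_new - U))
    U <- U_new
    Um <- U^m
    V <- crossprod(Um, X) / colSums(Um)
    if (delta < tol) break
  }
  list(U = U, V = V, iterations = it)
}

#' Fuzzy c-means clustering of a reduced dataset
#'
#' Standard alternating fuzzy c-means updates on the mean-centered data with
#' fuzziness exponent `m` (default 1.25), so each pixel carries a membership
#' in every class and boundary pixels can occupy several classes. Stops when
#' the largest membership change falls below `fcm_tol` or after
#' `fcm_max_iterations`. Scores are the membership maps (rows sum to 1);
#' loadings are the fuzzy centroids.
#'
#' @inheritParams run_kmeans
#' @return A [component_set()].
#' @export
run_fcm <- function(data, config = factorize_config(),
                    n_classes = config$n_components) {
  X <- center_matrix(data)
  if (n_classes > nrow(X)) stop("more classes than pixels")
  fit <- tryCatch(
    with_seed(config$seed, fcm_fit(X, n_classes, config$fcm_fuzziness,
                                   config$fcm_tol,
                                   config$fcm_max_iterations)),
    error = function(e) {
      if (!grepl("coincident centroids", conditionMessage(e))) stop(e)
      with_seed(config$seed + 1L,
                fcm_fit(X, n_classes, config$fcm_fuzziness, config$fcm_tol,
                        config$fcm_max_iterations))
    })
  U <- fit$U / rowSums(fit$U)
  ord <- order(colSums(U), decreasing = TRUE)
  component_set("fcm", U[, ord, drop = FALSE], fit$V[ord, , drop = FALSE],
                data$coords, data$features$mz,
                diagnostics = list(iterations = fit$iterations))
}

plsa_fit <- function(V, K, max_iter, rel_tol) {
  n <- nrow(V); F <- ncol(V)
  eps <- 1e-300
  tot <- sum(V)
  Ppz <- matrix(stats::runif(n * K) + 0.1, n, K)
  Ppz <- sweep(Ppz, 2, colSums(Ppz), "/")
  Pfz <- matrix(stats::runif(F * K) + 0.1, F, K)
  Pfz <- sweep(Pfz, 2, colSums(Pfz), "/")
  Pz <- rep(1 / K, K)
  ll <- numeric(0)
  nz <- V > 0
  for (it in seq_len(max_iter)) {
    M <- Ppz %*% (Pz * t(Pfz))               # n x F joint model
    ll[it] <- sum(V[nz] * log(M[nz] + eps))
    R <- V / (M + eps)
    Ppz_new <- sweep(Ppz * (R %*% Pfz), 2, Pz, "*")
    Pfz_new <- sweep(Pfz * (crossprod(R, Ppz)), 2, Pz, "*")
    Pz_new <- colSums(Ppz_new)
    Ppz <- sweep(Ppz_new, 2, pmax(Pz_new, eps), "/")
    Pfz <- sweep(Pfz_new, 2, pmax(colSums(Pfz_new), eps), "/")
    Pz <- Pz_new / sum(Pz_new)
    if (it >= 2L &&
        abs(ll[it] - ll[it - 1L]) < rel_tol * abs(ll[it - 1L])) break
  }
  list(Ppz = Ppz, Pfz = Pfz, Pz = Pz, loglik = ll)
}

#' Probabilistic latent semantic analysis of a reduced dataset
#'
#' Fits the aspect model `p(pixel, feature) = sum_z p(z) p(pixel|z)
#' p(feature|z)` by expectation-maximization on the raw non-negative matrix,
#' treating each pixel spectrum as a bag of feature counts. Latent aspects
#' correspond to tissue types with characteristic molecular signatures.
#' Stops when the relative log-likelihood change drops below `plsa_rel_tol`
#' (default 1e-5) or after `plsa_max_iterations` (default 500). Scores are
#' `p(pixel|z)` (columns sum to 1); loadings are `p(feature|z)` (rows sum to
#' 1). Components are ordered by descending aspect probability `p(z)`.
#'
#' @inheritParams run_pca
#' @return A [component_set()]; `diagnostics$loglik` is the EM trace and
#'   `diagnostics$pz` the aspect probabilities.
#' @export
run_plsa <- function(data, config = factorize_config()) {
  V <- data$matrix
  if (min(V) < 0) stop("PLSA requires non-negative input")
  if (sum(V) == 0) stop("PLSA requires a non-zero matrix")
  K <- config$n_components
  fit <- with_seed(config$seed,
                   plsa_fit(V, K, config$plsa_max_iterations,
                            config$plsa_rel_tol))
  ord <- order(fit$Pz, decreasing = TRUE)
  component_set("plsa", fit$Ppz[, ord, drop = FALSE],
                t(fit$Pfz)[ord, , drop = FALSE],
                data$coords, data$features$mz,
                diagnostics = list(loglik = fit$loglik, pz = fit$Pz[ord]))
}

#' Run several decompositions with one configuration
#'
#' @param data a `reduced_dataset` (TIC-normalized in the canonical
#'   pipeline).
#' @param methods character vector among `"pca"`, `"nnmf"`, `"maf"`,
#'   `"kmeans"`, `"fcm"`, `"plsa"`. The default is the five-method agreement
#'   set; k-means is exploratory and excluded by default.
#' @param config a [factorize_config()].
#' @return Named list of [component_set()] objects.
#' @export
run_methods <- function(data, methods = c("pca", "nnmf", "maf", "fcm",
                                          "plsa"),
                        config = factorize_config()) {
  runners <- list(pca = run_pca, nnmf = run_nnmf, maf = run_maf,
                  kmeans = run_kmeans, fcm = run_fcm, plsa = run_plsa)
  methods <- match.arg(methods, names(runners), several.ok = TRUE)
  out <- lapply(methods, function(m) runners[[m]](data, config))
  names(out) <- methods
  out
}
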