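# small in-code fixtures shared across test files

tiny_reduced <- function(n = 12, f = 4, seed = 1, normalization = "none") {
  set.seed(seed)
  nx <- ceiling(sqrt(n))
  coords <- cbind(x = rep(0:(nx - 1), length.out = n),
                  y = rep(0:(nx - 1), each = nx)[1:n])
  m <- matrix(stats::runif(n * f, 1, 10), n, f)
  reduced_dataset(coords, seq(3000, 3000 + 100 * (f - 1), by = 100),
                  m, normalization = "none", dataset_id = "tiny")
}

# two spatially separated blobs with distinct profiles, low noise
blob_reduced <- function(n_side = 10, f = 6, gap = 0.02, seed = 1) {
  set.seed(seed)
  nx <- n_side; ny <- n_side
  coords <- cbind(x = rep(0:(nx - 1), times = ny),
                  y = rep(0:(ny - 1), each = nx))
  left <- coords[, "x"] < nx / 2
  prof_a <- c(10, 8, 6, 1, 1, 1)[1:f]
  prof_b <- c(1, 1, 1, 10, 8, 6)[1:f]
  m <- t(vapply(seq_len(nrow(coords)), function(i) {
    p <- if (left[i]) prof_a else prof_b
    pmax(p + stats::rnorm(f, sd = gap), 0)
  }, numeric(f)))
  list(data = reduced_dataset(coords, seq(4000, 4000 + 250 * (f - 1), 250),
                              m, dataset_id = "blobs"),
       truth = left)
}

# quick phantom at reduced scale for fast pipeline-level tests
small_phantom_spec <- function(seed, ...) {
  phantom_spec(grid = c(24L, 20L),
               regions = list(list(cx = 6, cy = 6, rx = 4, ry = 3),
                              list(cx = 17, cy = 13, rx = 4, ry = 4)),
               n_shared = 30L, n_diff = 4L, seed = seed, ...)
}
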