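# Mini-batch k-means (Sculley-style): k-means++ initialisation, per-center
# counts as learning-rate schedule, final full-data assignment. Written here
# because the composition windows are clustered with the mini-batch variant
# specifically; plain stats::kmeans is used as an independent cross-check in
# the test suite, never as the implementation.

mini_batch_kmeans <- function(x, k, seed, batch_size = 1024L,
                              max_iter = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k) {
    abort(sprintf(
      "cannot fit %d clusters to %d windows; lower `n_initial_clusters`.",
      k, n
    ))
  }
  with_seed(seed, {
    centers <- kmeanspp_init(x, k)
    counts <- rep(0, k)
    batch_size <- min(batch_size, n)
    for (iter in seq_len(max_iter)) {
      batch <- sample.int(n, batch_size)
      xb <- x[batch, , drop = FALSE]
      a <- nearest_center(xb, centers)
      for (ci in unique(a)) {
        rows <- xb[a == ci, , drop = FALSE]
        for (r in seq_len(nrow(rows))) {
          counts[ci] <- counts[ci] + 1
          eta <- 1 / counts[ci]
          centers[ci, ] <- (1 - eta) * centers[ci, ] + eta * rows[r, ]
        }
      }
    }
    assignment <- nearest_center(x, centers)
    # reseed empty clusters from the windows farthest from their centers
    empty <- setdiff(seq_len(k), unique(assignment))
    if (length(empty) > 0) {
      d <- rowSums((x - centers[assignment, , drop = FALSE])^2)
      far <- order(d, decreasing = TRUE)[seq_along(empty)]
      centers[empty, ] <- x[far, , drop = FALSE]
      assignment <- nearest_center(x, centers)
      empty <- setdiff(seq_len(k), unique(assignment))
      if (length(empty) > 0) {
        warn(sprintf("%d cluster(s) remained empty after reseeding.",
                     length(empty)))
      }
    }
    inertia <- sum((x - centers[assignment, , drop = FALSE])^2)
    list(centers = centers, assignment = assignment, inertia = inertia,
         empty = empty)
  })
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- colSums((t(x) - x[idx[1], ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[j + 1] <- sample.int(n, 1)
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, colSums((t(x) - x[idx[j + 1], ])^2))
  }
  x[idx, , drop = FALSE]
}

# index of nearest center for every row of x (squared Euclidean)
nearest_center <- function(x, centers) {
  cross <- x %*% t(centers)
  d2 <- outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * cross
  max.col(-d2, ties.method = "first")
}
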