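# small composition matrix with two well-separated groups
two_group_comp <- function(n_per = 6, seed = 2) {
  set.seed(seed)
  tumor <- cbind(0.9 + runif(n_per, 0, 0.1), 0, 0, 0, 0, 0, 0,
                 0.1 - runif(n_per, 0, 0.1))
  stroma <- cbind(0.1 - runif(n_per, 0, 0.1), 0, 0, 0, 0, 0, 0,
                  0.9 + runif(n_per, 0, 0.1))
  m <- rbind(tumor, stroma)
  m <- m / rowSums(m)
  colnames(m) <- cell_type_vocabulary()
  m
}

test_that("two separated composition groups are split exactly at k = 2", {
  comp <- two_group_comp()
  fit <- cluster_windows(comp, k = 2, seed = 7)
  got <- fit$assignment
  # exhaustive oracle: best 2-partition by within-cluster sum of squares
  n <- nrow(comp)
  best <- NULL
  best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    part <- as.integer(intToBits(code))[1:n]
    ss <- 0
    for (g in 0:1) {
      rows <- comp[part == g, , drop = FALSE]
      if (nrow(rows) == 0) next
      ss <- ss + sum(sweep(rows, 2, colMeans(rows))^2)
    }
    if (ss < best_ss) {
      best_ss <- ss
      best <- part
    }
  }
  same_partition <- function(a, b) {
    all(rowSums(table(a, b) > 0) == 1) && all(colSums(table(a, b) > 0) == 1)
  }
  expect_true(same_partition(got, best))
  # independent library cross-check on the same data
  km <- stats::kmeans(comp, centers = 2, nstart = 10)
  expect_true(same_partition(got, km$cluster))
})

test_that("clustering is deterministic and validates its inputs", {
  comp <- two_group_comp(20, seed = 5)
  f1 <- cluster_windows(comp, k = 4, seed = 11)
  f2 <- cluster_windows(comp, k = 4, seed = 11)
  expect_identical(f1$assignment, f2$assignment)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(nrow(cluster_windows(comp, k = 10, seed = 1)$centroids),
                   10L)
  expect_error(cluster_windows(comp[1:5, ], k = 10), "lower")
})

test_that("enrichment scores standardize type columns across neighborhoods", {
  comp <- two_group_comp(10)
  assignment <- rep(1:2, each = 10)
  z <- enrichment_scores(assignment, comp, merge_map = c(1L, 2L))
  expect_equal(unname(colMeans(z)), rep(0, 8), tolerance = 1e-9)
  # the tumor-pure neighborhood scores maximal on the Tumor column
  expect_identical(which.max(z[, "Tumor"]),
                   which.min(z[, "Stroma"]))
  # zero-variance convention: a type absent everywhere scores 0
  expect_true(all(z[, "CD8_T"] == 0))
  # identical mean compositions score 0 everywhere
  same <- matrix(0.125, nrow = 10, ncol = 8,
                 dimnames = list(NULL, cell_type_vocabulary()))
  z0 <- enrichment_scores(rep(1:2, 5), same, c(1L, 2L))
  expect_true(all(z0 == 0))
})

test_that("merging collapses identical centroids and respects explicit maps", {
  centro <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0),
                  c(1, 0, 0, 0, 0, 0, 0, 0),
                  c(0, 0, 0, 0, 0, 0, 0, 1))
  clust <- list(centroids = centro, assignment = c(1, 1, 2, 3, 3, 3, 3))
  mm <- merge_neighborhoods(clust, mode = "auto_threshold", threshold = 0.05)
  expect_identical(mm[1], mm[2]) # zero cosine distance: merged
  expect_false(mm[1] == mm[3]) # orthogonal support: kept apart
  # final ids ordered by window count: cluster 3 has most windows -> CN1
  expect_identical(mm[3], 1L)
  # identity explicit map keeps n_final = n_initial
  mm_id <- merge_neighborhoods(clust, mode = "explicit_map", map = 1:3)
  expect_identical(length(unique(mm_id)), 3L)
  expect_error(merge_neighborhoods(clust, mode = "explicit_map", map = c(1, 2)),
               "every initial cluster")
})

test_that("cells inherit their window's cluster and merging only coarsens", {
  cfg <- synth_config(n_patients = 2, cells_per_spot = 400, seed = 23)
  cells <- assign_cell_types(simulate_cohort(cfg)$cells)
  fit <- detect_neighborhoods(cells, k = 8, seed = 23)
  expect_false(anyNA(fit$cells$cn_final))
  expect_identical(nrow(fit$cells), nrow(cells))
  # coarsening: cells sharing an initial cluster share a final CN
  split_check <- fit$cells |>
    dplyr::distinct(cn_initial, cn_final) |>
    dplyr::count(cn_initial)
  expect_true(all(split_check$n == 1))
  expect_lte(fit$n_final, fit$k_initial)
  # determinism end to end
  fit2 <- detect_neighborhoods(cells, k = 8, seed = 23)
  expect_identical(fit$cells, fit2$cells)
})

test_that("a pure-tumor spot collapses to a single neighborhood", {
  set.seed(3)
  cells <- grid_cells(cbind(runif(60, 0, 100), runif(60, 0, 100)),
                      rep("Tumor", 60))
  cells$patient_id <- "P1"
  suppressWarnings(
    fit <- detect_neighborhoods(cells, window_size = 5, k = 2, seed = 3)
  )
  expect_identical(fit$n_final, 1L)
  expect_true(all(fit$cells$cn_final == "CN1"))
})

test_that("per-patient CN frequencies count cells and sum to one", {
  cells <- tibble::tibble(
    patient_id = c(rep("A", 10), rep("B", 4)),
    cn_final = factor(c(rep("CN1", 4), rep("CN2", 6), rep("CN2", 4)),
                      levels = c("CN1", "CN2"))
  )
  f <- cn_frequencies(cells)
  fa <- f[f$patient_id == "A", ]
  expect_equal(fa$frequency[fa$cn_final == "CN1"], 0.4)
  expect_equal(fa$frequency[fa$cn_final == "CN2"], 0.6)
  sums <- tapply(f$frequency, f$patient_id, sum)
  expect_equal(as.vector(sums), rep(1, 2))
  # pooled cohort frequency equals the cell-count-weighted patient mean
  pooled <- mean(cells$cn_final == "CN1")
  weights <- c(10, 4) / 14
  expect_equal(sum(f$frequency[f$cn_final == "CN1"] * weights), pooled)
})

test_that("tidy and glance summarise the fitted model", {
  cfg <- synth_config(n_patients = 1, cells_per_spot = 300, seed = 29)
  cells <- assign_cell_types(simulate_spot(cfg, "P1"))
  cells$patient_id <- "P1"
  fit <- detect_neighborhoods(cells, k = 6, seed = 29)
  td <- tidy(fit)
  expect_identical(nrow(td), fit$n_final * 8L)
  expect_setequal(unique(td$cell_type), cell_type_vocabulary())
  gl <- glance(fit)
  expect_identical(gl$n_windows, nrow(cells))
  expect_identical(gl$window_size, 10)
  expect_s3_class(autoplot(fit), "ggplot")
})
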