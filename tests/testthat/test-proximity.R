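test_that("nearest distances reproduce hand geometry", {
  cells <- grid_cells(rbind(c(0, 0), c(3, 4)), c("CD8_T", "Tumor"))
  d <- nearest_distances(cells, "CD8_T", "Tumor")
  expect_equal(d$distance, 5)
  # self-distance with exclude_self: two CD8 cells 2 um apart both report 2
  pair <- grid_cells(rbind(c(0, 0), c(2, 0)), c("CD8_T", "CD8_T"))
  ds <- nearest_distances(pair, "CD8_T", "CD8_T", exclude_self = TRUE)
  expect_equal(ds$distance, c(2, 2))
  # without exclusion the nearest target is the cell itself
  ds0 <- nearest_distances(pair, "CD8_T", "CD8_T", exclude_self = FALSE)
  expect_equal(ds0$distance, c(0, 0))
})

test_that("random spots match the brute-force nearest-target oracle", {
  for (seed in 1:5) {
    cells <- random_spot(50, seed = seed)
    got <- nearest_distances(cells, "CD8_T", "Tumor")
    expect_equal(got$distance, oracle_nearest(cells, "CD8_T", "Tumor"))
    self <- nearest_distances(cells, "Stroma", "Stroma")
    expect_equal(self$distance, oracle_nearest(cells, "Stroma", "Stroma"))
  }
})

test_that("missing target populations yield NA distances, excluded from means", {
  cells <- grid_cells(rbind(c(0, 0), c(1, 0)), c("CD8_T", "CD8_T"))
  expect_message(d <- nearest_distances(cells, "CD8_T", "B_cell"),
                 "no eligible")
  expect_true(all(is.na(d$distance)))
  expect_identical(nrow(mean_nearest_distance(d)), 0L)
})

test_that("per-spot means average the defined distances", {
  d <- tibble::tibble(patient_id = "P1", spot_id = "s1",
                      distance = c(1, 3))
  expect_equal(mean_nearest_distance(d)$mean_distance, 2)
  expect_equal(mean_nearest_distance(d[1, ])$mean_distance, 1)
  expect_equal(mean_nearest_distance(d[2:1, ])$mean_distance, 2)
})

test_that("spatial scores follow the nearest-A over nearest-B ratio", {
  # CD8 center with tumor at 6 um and CD4 at 2 um -> score 3
  cells <- grid_cells(rbind(c(0, 0), c(6, 0), c(0, 2)),
                      c("CD8_T", "Tumor", "CD4_T"))
  sc <- spatial_scores(cells)
  expect_equal(sc$score, 3)
  expect_equal(spatial_score_by_spot(sc)$spatial_score, 3)
  # equidistant configuration scores exactly 1
  eq <- grid_cells(rbind(c(0, 0), c(5, 0), c(0, 5)),
                   c("CD8_T", "Tumor", "CD4_T"))
  expect_equal(spatial_scores(eq)$score, 1)
})

test_that("spatial scores equal the oracle composition on random spots", {
  cells <- random_spot(80, seed = 12)
  sc <- spatial_scores(cells)
  oa <- oracle_nearest(cells, "CD8_T", "Tumor")
  ob <- oracle_nearest(cells, "CD8_T", "CD4_T")
  expect_equal(sc$score, oa / ob)
  # per-spot aggregation modes
  expect_equal(spatial_score_by_spot(sc)$spatial_score, mean(oa / ob))
  expect_equal(
    spatial_score_by_spot(sc, "ratio_of_means")$spatial_score,
    mean(oa) / mean(ob)
  )
})

test_that("distances scale with coordinates while scores stay invariant", {
  cells <- random_spot(60, seed = 3)
  scaled <- dplyr::mutate(cells, x_um = x_um * 2.5, y_um = y_um * 2.5)
  d1 <- nearest_distances(cells, "CD8_T", "Tumor")$distance
  d2 <- nearest_distances(scaled, "CD8_T", "Tumor")$distance
  expect_equal(d2, 2.5 * d1)
  expect_equal(spatial_scores(scaled)$score, spatial_scores(cells)$score)
})

test_that("CN stratification partitions the defined distances", {
  cells <- random_spot(100, seed = 7)
  cells$cn_final <- factor(sample(c("CN1", "CN2", "CN3"), 100, TRUE))
  d <- nearest_distances(cells, "CD8_T", "Tumor")
  strat <- distances_by_cn(d, designated_cn = "CN3")
  expect_identical(nrow(strat), sum(!is.na(d$distance)))
  expect_identical(sum(strat$in_designated) + sum(!strat$in_designated),
                   nrow(strat))
  # all sources in the designated CN -> empty "other" stratum
  cells$cn_final <- factor("CN3", levels = c("CN1", "CN3"))
  d3 <- nearest_distances(cells, "CD8_T", "Tumor")
  s3 <- distances_by_cn(d3, designated_cn = "CN3")
  expect_identical(sum(!s3$in_designated), 0L)
})

test_that("planted geometry separates in-CN from out-of-CN tumor distances", {
  # lymphocyte domain far from the tumor domain: CD8 cells inside the
  # lymphoid region must sit farther from tumor cells than CD8 cells
  # elsewhere
  set.seed(41)
  n <- 150
  lymph <- cbind(runif(n, 0, 200), runif(n, 0, 200))
  mixed <- cbind(runif(n, 800, 1000), runif(n, 0, 200))
  cells <- grid_cells(
    rbind(lymph, mixed),
    c(sample(c("CD8_T", "CD4_T"), n, TRUE),
      sample(c("CD8_T", "Tumor"), n, TRUE))
  )
  cells$cn_final <- factor(rep(c("CN3", "CN2"), each = n))
  d <- nearest_distances(cells, "CD8_T", "Tumor")
  strat <- distances_by_cn(d, designated_cn = "CN3")
  expect_gt(mean(strat$distance[strat$in_designated]),
            mean(strat$distance[!strat$in_designated]))
})
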