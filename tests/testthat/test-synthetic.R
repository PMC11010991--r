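test_that("a degenerate single-archetype config yields a pure tumor spot", {
  arch <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0), nrow = 1,
                 dimnames = list("OnlyTumor", cell_type_vocabulary()))
  cfg <- synth_config(n_patients = 1, cells_per_spot = 200,
                      archetypes = arch, risk_cn = "OnlyTumor", seed = 5)
  spot <- simulate_spot(cfg, "P1")
  expect_true(all(spot$true_cell_type == "Tumor"))
  em <- default_marker_emission()
  midpoint <- exp((em$meanlog_positive + em$meanlog_negative) / 2)
  expect_true(all(spot$PanCK_intensity > midpoint))
  expect_true(all(spot$DAPI_intensity > midpoint))
})

test_that("generation is deterministic given the config seed", {
  cfg <- synth_config(n_patients = 2, cells_per_spot = 150, seed = 99)
  expect_identical(simulate_cohort(cfg)$cells, simulate_cohort(cfg)$cells)
  expect_identical(simulate_spot(cfg, "P1"), simulate_spot(cfg, "P1"))
  # different seeds diverge
  cfg2 <- synth_config(n_patients = 2, cells_per_spot = 150, seed = 100)
  expect_false(identical(simulate_cohort(cfg)$cells,
                         simulate_cohort(cfg2)$cells))
})

test_that("empirical type frequencies converge to the archetype row", {
  # one region, 50/50 CD8/CD4 archetype, n = 10,000: binomial sd ~ 0.005,
  # so +/- 0.02 is a 4-sd band
  arch <- matrix(0, nrow = 1, ncol = 8,
                 dimnames = list("Split", cell_type_vocabulary()))
  arch[1, c("CD8_T", "CD4_T")] <- 0.5
  cfg <- synth_config(n_patients = 1, cells_per_spot = 10000,
                      archetypes = arch, risk_cn = "Split", seed = 21)
  spot <- simulate_spot(cfg, "P1")
  freq <- table(spot$true_cell_type) / nrow(spot)
  expect_lt(abs(freq[["CD8_T"]] - 0.5), 0.02)
  expect_lt(abs(freq[["CD4_T"]] - 0.5), 0.02)
})

test_that("spots respect the stated geometry and ground-truth contract", {
  cfg <- synth_config(n_patients = 3, cells_per_spot = c(200, 300), seed = 8)
  coh <- simulate_cohort(cfg)
  r <- cfg$spot_diameter / 2
  d_centre <- sqrt((coh$cells$x_um - r)^2 + (coh$cells$y_um - r)^2)
  expect_true(all(d_centre <= r + 1e-9))
  expect_true(all(!is.na(coh$cells$true_cn)))
  expect_true(all(coh$cells$true_cn %in% rownames(cfg$archetypes)))
  expect_identical(nrow(coh$survival), 3L)
  expect_setequal(coh$survival$patient_id, unique(coh$cells$patient_id))
  # region contiguity proxy: every (spot, region) is non-empty and carries
  # exactly one archetype
  per_region <- dplyr::distinct(coh$cells, spot_id, region_id, true_cn)
  expect_identical(nrow(per_region),
                   nrow(dplyr::distinct(per_region, spot_id, region_id)))
})

test_that("archetype rows must lie on the simplex", {
  bad <- default_archetypes()
  bad[1, 1] <- bad[1, 1] + 0.05
  expect_error(synth_config(archetypes = bad), "summing to 1")
  expect_error(synth_config(censoring_rate = 1), "censoring_rate")
  expect_error(synth_config(spot_diameter = 0), "spot_diameter")
})

test_that("survival times follow the planted frequency-dependent hazard", {
  cfg <- synth_config(survival_beta = 0, censoring_rate = 0,
                      max_followup = 1e6, survival_baseline = 0.05)
  # beta = 0: times are iid exponential(0.05); mean ~ 20 months
  sv <- simulate_survival(rep(c(0.1, 0.9), each = 2500), cfg, seed = 4)
  expect_true(all(sv$event == 1))
  expect_equal(mean(sv$time_months), 20, tolerance = 0.05)
  # beta > 0: high-frequency patients die faster on average
  cfg3 <- synth_config(survival_beta = 3, censoring_rate = 0,
                       max_followup = 1e6, survival_baseline = 0.05)
  sv3 <- simulate_survival(rep(c(0.1, 0.9), each = 2500), cfg3, seed = 4)
  m_low <- mean(sv3$time_months[1:2500])
  m_high <- mean(sv3$time_months[2501:5000])
  expect_gt(m_low / m_high, exp(3 * 0.8) * 0.8)
})
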