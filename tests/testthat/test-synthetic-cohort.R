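test_that("ground-truth covariance encodes the planted structure entrywise", {
  cfg <- cohort_config(base_correlation = 0.6, patient_rich_deficit = 0.2,
                       duration_effect = 0.002, deficit_scope = "block")
  rich <- 1:9

  hc <- build_ground_truth_covariance(cfg, "HC", duration = 999)
  expect_equal(unique(hc[rich, rich][upper.tri(diag(9))]), 0.6)
  expect_equal(diag(hc), rep(1, 90), ignore_attr = TRUE)
  expect_equal(hc, t(hc))

  # null effect: patient covariance identical to control covariance
  cfg0 <- cohort_config(patient_rich_deficit = 0, duration_effect = 0)
  expect_equal(build_ground_truth_covariance(cfg0, "JME", 50),
               build_ground_truth_covariance(cfg0, "HC"))

  # entrywise formula: 0.6 - 0.2 - 0.002 * 50 = 0.3
  jme <- build_ground_truth_covariance(cfg, "JME", duration = 50)
  expect_equal(unique(jme[rich, rich][upper.tri(diag(9))]),
               0.6 - 0.2 - 0.002 * 50)

  # hub scope touches only hub-incident rich entries
  cfg_h <- cohort_config(base_correlation = 0.6, patient_rich_deficit = 0.2,
                         duration_effect = 0.002, deficit_scope = "hub")
  jme_h <- build_ground_truth_covariance(cfg_h, "JME", duration = 50)
  expect_equal(unname(jme_h[1, 2:9]), rep(0.3, 8))
  expect_equal(jme_h[2:9, 2:9], hc[2:9, 2:9])

  # floored at zero
  cfg_f <- cohort_config(base_correlation = 0.2, patient_rich_deficit = 0.9)
  jme_f <- build_ground_truth_covariance(cfg_f, "JME", duration = 10)
  expect_equal(unname(jme_f[1, 2]), 0)
})

test_that("planted covariances are positive semidefinite, with repair total", {
  for (cfg in list(cohort_config(),
                   cohort_config(deficit_scope = "block"),
                   cohort_config(base_correlation = 0.8,
                                 background_correlation = 0.7,
                                 feeder_correlation = 0.65))) {
    for (g in c("HC", "JME")) {
      C <- build_ground_truth_covariance(cfg, g, duration = 84)
      expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
      expect_equal(diag(C), rep(1, nrow(C)), ignore_attr = TRUE)
    }
  }
})

test_that("cohort generation is bit-identical given the seed", {
  cfg <- scaled_config(seed = 11)
  p1 <- generate_cohort(cfg, qc_check = FALSE)
  p2 <- generate_cohort(cfg, qc_check = FALSE)
  expect_identical(p1, p2)
  p3 <- generate_cohort(scaled_config(seed = 12), qc_check = FALSE)
  expect_false(identical(p1$subjects[[1]]$series, p3$subjects[[1]]$series))
})

test_that("perfectly correlated noiseless signals give sample r = 1", {
  cfg <- cohort_config(n_regions = 2, rich_set_size = 2, n_subjects_per_group = 1,
                       n_timepoints = 50, base_correlation = 1, noise_sd = 0,
                       patient_rich_deficit = 0, duration_effect = 0)
  panel <- generate_cohort(cfg, qc_check = FALSE)
  r <- pearson_matrix(panel$subjects[[1]]$series)$values
  expect_equal(r[1, 2], 1, tolerance = 1e-12)
})

test_that("observed rich-block correlation matches the designated value", {
  # the observation-noise construction must not attenuate correlations:
  # the mean HC rich-block sample correlation sits within 3 SE of base
  cfg <- cohort_config(seed = 5)
  panel <- generate_cohort(cfg, qc_check = FALSE)
  rich <- 1:9
  per_subject <- vapply(panel_subjects(panel, "HC"), function(s) {
    r <- pearson_matrix(s$series)$values
    mean(r[rich, rich][upper.tri(diag(9))])
  }, numeric(1))
  se <- sd(per_subject) / sqrt(length(per_subject))
  expect_lt(abs(mean(per_subject) - cfg$base_correlation), 3 * se)
})

test_that("control mean network obeys the construction rules", {
  panel <- generate_cohort(cohort_config(seed = 3))  # qc_check on
  pn <- panel_networks(panel)
  qc <- network_checks(mean_binary_network(
    group_mean_network(pn$nets[pn$groups == "HC"])))
  expect_true(qc$pass)
  expect_gte(qc$density, 0.10)
  expect_lte(qc$density, 0.50)
  expect_gt(qc$mean_degree, 2 * log(90))
  expect_length(qc$isolated, 0)
})

test_that("a structureless configuration fails the generation quality gate", {
  cfg <- cohort_config(n_subjects_per_group = 4, n_timepoints = 60,
                       base_correlation = 0.05, background_correlation = 0.05,
                       feeder_correlation = 0.05, seed = 2)
  expect_error(generate_cohort(cfg), "construction rules")
})

test_that("larger planted deficits weakly decrease patient rich-connection sums", {
  deficits <- c(0.05, 0.15, 0.30)
  means <- sapply(deficits, function(d) {
    reps <- vapply(1:20, function(r) {
      cfg <- scaled_config(seed = 100 + r, patient_rich_deficit = d,
                           deficit_scope = "block")
      panel <- generate_cohort(cfg, qc_check = FALSE)
      pn <- panel_networks(panel)
      rich <- select_rich_nodes(group_mean_network(pn$nets[pn$groups == "HC"]))
      jme <- pn$nets[pn$groups == "JME"]
      mean(vapply(jme, function(nt)
        decompose_connections(nt, rich)$rich_sum, numeric(1)))
    }, numeric(1))
    mean(reps)
  })
  expect_true(all(diff(means) <= 0))
})
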