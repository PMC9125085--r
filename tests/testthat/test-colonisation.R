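test_that("candidate pool applies the exclusion rules of the design", {
  fix <- toy_colonisation()
  det <- detection_table(fix$counts, fix$metadata)
  pool <- candidate_pool(det)
  oracle <- oracle_classify(fix$counts, fix$metadata)
  expect_setequal(pool, oracle$pool)
  expect_setequal(pool, c("a_snow_only", "a_one_day", "a_all_days", "a_gap"))

  # the narrower control reading readmits the FT-only exclusion
  pool_soil_only <- candidate_pool(det, include_control_ft = FALSE)
  expect_setequal(pool_soil_only, c(pool, "a_in_ctrl_ft"))

  no_snow <- dplyr::filter(det, compartment != "snow")
  expect_error(candidate_pool(no_snow), "snow")
})

test_that("classification follows the invader/colonist/successful chain", {
  fix <- toy_colonisation()
  det <- detection_table(fix$counts, fix$metadata)
  calls <- classify_colonists(det)
  status_of <- function(id) {
    as.character(calls$status[calls$asv_id == id])
  }
  expect_equal(status_of("a_one_day"), "invader")
  expect_equal(status_of("a_all_days"), "successful_colonist")
  # detection gap between D5 and D29 does not disqualify
  expect_equal(status_of("a_gap"), "successful_colonist")
  expect_equal(status_of("a_in_control"), "excluded")
  expect_equal(status_of("a_snow_only"), "candidate")
  expect_false("soil_backgrnd" %in% calls$asv_id)

  # agreement with the loop-based oracle for pool members
  oracle <- oracle_classify(fix$counts, fix$metadata)$calls
  merged <- dplyr::inner_join(
    dplyr::mutate(tidy(calls), status = as.character(status)),
    oracle, by = c("asv_id", "experiment", "condition"),
    suffix = c("", "_oracle")
  )
  expect_gt(nrow(merged), 0)
  expect_equal(merged$status, merged$status_oracle)
})

test_that("per-unit counts are cumulative and match the fixture", {
  fix <- toy_colonisation()
  det <- detection_table(fix$counts, fix$metadata)
  calls <- classify_colonists(det)
  counts <- summarize_colonisation(calls)
  expect_equal(counts$invaders, 3)
  expect_equal(counts$colonists, 2)
  expect_equal(counts$successful, 2)
  expect_true(all(counts$invaders >= counts$colonists))
  expect_true(all(counts$colonists >= counts$successful))

  ov <- colonisation_overview(calls)
  expect_equal(ov$pool_size, 4)
  expect_equal(ov$global_invaders, 3)
  expect_equal(ov$noninvading_snow_unique, 1)

  empty <- calls[0, ]
  zero <- summarize_colonisation(empty)
  expect_equal(nrow(zero), 0)
})

test_that("pool minus invaders equals the snow-unique remainder", {
  expect_equal(non_invading_pool(541, 16), 525)
  expect_error(non_invading_pool(10, 11), "exceed")
})

test_that("nested-set chain holds on noisy simulated data", {
  for (seed in 1:3) {
    sim <- simulate_microcosm(simulation_config(
      seed = seed, n_soil_taxa = 60, n_snow_taxa = 30, n_shared_taxa = 10,
      n_planted = 8, reads_per_sample = 3000,
      survival_prob = 0.6, detection_probability = 0.8
    ))
    det <- detection_table(sim$counts, sim$metadata)
    pool <- candidate_pool(det)
    calls <- classify_colonists(det, pool = pool)
    succ <- calls$asv_id[calls$status >= "successful_colonist"]
    colo <- calls$asv_id[calls$status >= "potential_colonist"]
    inva <- calls$asv_id[calls$status >= "invader"]
    expect_true(all(succ %in% colo))
    expect_true(all(colo %in% inva))
    expect_true(all(inva %in% pool))
    # exclusion is airtight: pool never intersects control/pre-treatment hits
    det_hit <- dplyr::filter(det, detected)
    excluded_set <- union(
      det_hit$asv_id[det_hit$arm %in% "control" &
                       det_hit$compartment %in% c("soil", "flow_through")],
      det_hit$asv_id[det_hit$compartment == "soil" &
                       as.character(det_hit$day) %in% pre_treatment_days()]
    )
    expect_length(intersect(pool, excluded_set), 0)
  }
})

test_that("raising the detection threshold never adds invaders", {
  sim <- simulate_microcosm(simulation_config(
    seed = 9, n_soil_taxa = 60, n_snow_taxa = 30, n_shared_taxa = 10,
    n_planted = 8, reads_per_sample = 1000, detection_probability = 0.9
  ))
  # pool fixed at the base threshold: raising the threshold only removes
  # treated-soil detections, so the invader count cannot grow
  base_pool <- candidate_pool(detection_table(sim$counts, sim$metadata))
  n_invaders <- vapply(c(1, 2, 5, 10), function(thr) {
    det <- detection_table(sim$counts, sim$metadata, threshold = thr)
    calls <- classify_colonists(det, pool = base_pool)
    length(unique(calls$asv_id[calls$status >= "invader"]))
  }, numeric(1))
  expect_true(all(diff(n_invaders) <= 0))
})

test_that("per-replicate recounting matches a brute-force oracle", {
  sim <- simulate_microcosm(simulation_config(
    seed = 4, n_soil_taxa = 40, n_snow_taxa = 20, n_shared_taxa = 5,
    n_planted = 6, reads_per_sample = 2000,
    survival_prob = 0.5, detection_probability = 0.8
  ))
  det <- detection_table(sim$counts, sim$metadata)
  rc <- replicate_colonist_counts(det)
  oracle <- oracle_classify(sim$counts, sim$metadata, by_replicate = TRUE)
  ocounts <- oracle$calls |>
    dplyr::group_by(experiment, condition, replicate) |>
    dplyr::summarise(
      invaders = sum(status != "candidate"),
      colonists = sum(status %in% c("potential_colonist",
                                    "successful_colonist")),
      successful = sum(status == "successful_colonist"),
      .groups = "drop"
    )
  merged <- dplyr::inner_join(rc, ocounts,
                              by = c("experiment", "condition", "replicate"),
                              suffix = c("", "_o"))
  expect_equal(nrow(merged), nrow(rc))
  expect_equal(merged$invaders, merged$invaders_o)
  expect_equal(merged$colonists, merged$colonists_o)
  expect_equal(merged$successful, merged$successful_o)
})

test_that("identical replicates across units give F = 0, p = 1", {
  rc <- tidyr::expand_grid(
    experiment = "melt_rate", condition = c("average", "fast"),
    replicate = 1:3
  )
  rc$invaders <- 5L
  rc$colonists <- 3L
  rc$successful <- 1L
  res <- colonist_counts_anova(rc)
  expect_equal(res$statistic, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
  expect_error(colonist_counts_anova(rc[rc$replicate == 1, ]), "replicate")
})

test_that("a planted invader-rate difference is detected with high power", {
  pvals <- vapply(1:100, function(seed) {
    sim <- simulate_microcosm(simulation_config(
      seed = seed, n_soil_taxa = 40, n_snow_taxa = 20, n_shared_taxa = 5,
      n_planted = 10, reads_per_sample = 1000,
      planted_per_condition = c(average = 10, fast = 2, acidic = 2,
                                alkaline = 2),
      detection_probability = 0.9
    ))
    det <- detection_table(sim$counts, sim$metadata)
    res <- colonist_counts_anova(replicate_colonist_counts(det))
    res$p_value[res$category == "invaders"]
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.8)
})

test_that("heatmap table enumerates invader x replicate x day cells", {
  fix <- toy_colonisation()
  # extend the fixture so each replicate covers the same days
  det <- detection_table(fix$counts, fix$metadata)
  calls <- classify_colonists(det)
  relabund <- transform_relative_abundance(fix$counts)
  ht <- heatmap_table(calls, relabund, fix$metadata)
  # 3 invaders x sampled (replicate, day) combinations: r1 x {D5, D9, D29},
  # r2 x {D5}
  expect_equal(nrow(ht), 3 * 4)
  expect_true(all(ht$relative_abundance >= 0))

  # values equal direct relabund lookups
  md <- validate_metadata(fix$metadata)
  for (i in seq_len(nrow(ht))) {
    sid <- md$sample_id[
      md$compartment == "soil" & md$arm %in% "treatment" &
        md$condition %in% ht$condition[i] & md$replicate == ht$replicate[i] &
        as.character(md$day) == ht$day[i]
    ]
    expect_equal(ht$relative_abundance[i],
                 relabund[[sid]][relabund$asv_id == ht$asv_id[i]])
  }

  none <- calls[calls$status < "invader", ]
  class(none) <- class(calls)
  empty <- heatmap_table(none, relabund, fix$metadata)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("asv_id", "day", "relative_abundance", "status")
                  %in% names(empty)))
})
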