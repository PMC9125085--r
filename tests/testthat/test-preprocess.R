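test_that("presence calls follow the threshold and are monotone in it", {
  counts <- tibble::tibble(asv_id = c("a", "b"), s1 = c(0L, 1L),
                           s2 = c(3L, 2L))
  pm <- presence_matrix(counts, 1)
  expect_false(pm["a", "s1"])
  expect_true(pm["b", "s1"])

  set.seed(41)
  rnd <- dplyr::bind_cols(
    tibble::tibble(asv_id = paste0("a", 1:5)),
    tibble::as_tibble(matrix(rpois(25, 1), 5, 5,
                             dimnames = list(NULL, paste0("s", 1:5))))
  )
  for (thr in 2:4) {
    lo <- presence_matrix(rnd, thr - 1)
    hi <- presence_matrix(rnd, thr)
    expect_true(all(lo[hi]))  # every detection at thr survives at thr - 1
  }
})

test_that("prevalence score matches exhaustive hypergeometric enumeration", {
  # independent oracle: enumerate the tail by summing binomial products
  oracle <- function(k_neg, k_true, n_neg, n_true) {
    total_det <- k_neg + k_true
    n <- n_neg + n_true
    num <- 0
    for (j in k_neg:min(n_neg, total_det)) {
      num <- num + choose(n_neg, j) * choose(n_true, total_det - j)
    }
    num / choose(n, total_det)
  }
  expect_equal(oracle(2, 1, 3, 20), 61 / 1771)
  expect_equal(prevalence_score(2, 1, 3, 20), 61 / 1771, tolerance = 1e-12)

  for (n_neg in 1:12) {
    for (n_true in 1:12) {
      for (k_neg in 0:n_neg) {
        for (k_true in 0:n_true) {
          if (k_neg + k_true == 0) next
          expect_equal(
            prevalence_score(k_neg, k_true, n_neg, n_true),
            oracle(k_neg, k_true, n_neg, n_true),
            tolerance = 1e-10
          )
        }
      }
    }
  }
})

test_that("contaminant calls follow prevalence enrichment in negatives", {
  # asv ctrl-only: 3/3 negatives, 0/10 true; asv clean: absent from negatives;
  # asv borderline: 2/3 negatives vs 1/20 true needs > 10 true samples, so
  # build 3 negatives + 20 true samples
  n_true <- 20
  neg <- paste0("neg", 1:3)
  tru <- paste0("t", seq_len(n_true))
  counts <- dplyr::bind_cols(
    tibble::tibble(asv_id = c("ctrl_only", "clean", "borderline", "filler")),
    tibble::as_tibble(rbind(
      c(rep(5L, 3), rep(0L, n_true)),
      c(rep(0L, 3), rep(4L, n_true)),
      c(2L, 2L, 0L, 1L, rep(0L, n_true - 1)),
      rep(1L, 3 + n_true)
    ), .name_repair = "minimal") |> rlang::set_names(c(neg, tru))
  )
  rep_tbl <- filter_contaminants_prevalence(counts, neg)
  rep_tbl <- rep_tbl[match(counts$asv_id, rep_tbl$asv_id), ]
  expect_equal(rep_tbl$is_contaminant,
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rep_tbl$score[3], 61 / 1771, tolerance = 1e-10)
  expect_true(all(rep_tbl$score >= 0 & rep_tbl$score <= 1))
  expect_error(filter_contaminants_prevalence(counts, character(0)),
               "negative")
})

test_that("control-abundance curation discards only control-enriched ASVs", {
  counts <- tibble::tibble(
    asv_id = c("hot", "cold", "absent", "even"),
    kit = c(100L, 1L, 0L, 10L),
    s1 = c(1L, 500L, 300L, 199L),
    s2 = c(1L, 500L, 300L, 199L)
  )
  out <- curate_control_abundance(counts, "kit")
  # spreadsheet oracle: mean relabund in kit vs mean over s1, s2
  rel <- sweep(as.matrix(counts[-1]), 2, colSums(as.matrix(counts[-1])), "/")
  should_drop <- counts$asv_id[rel[, 1] > rowMeans(rel[, 2:3])]
  expect_setequal(out$discarded, should_drop)
  expect_equal(out$discarded, "hot")
  expect_true("absent" %in% out$retained$asv_id)
})

test_that("cleanup never removes an ASV absent from every control sample", {
  sim <- simulate_microcosm(simulation_config(
    seed = 5, n_soil_taxa = 60, n_snow_taxa = 30, n_shared_taxa = 10,
    n_planted = 5, reads_per_sample = 2000
  ))
  labs <- sim$metadata$sample_id[sim$metadata$compartment == "lab_control"]
  pm <- presence_matrix(sim$counts)
  never_in_controls <- rownames(pm)[rowSums(pm[, labs, drop = FALSE]) == 0]
  cur <- curate_control_abundance(sim$counts, labs)
  rep_tbl <- filter_contaminants_prevalence(cur$retained, labs)
  removed <- union(cur$discarded, rep_tbl$asv_id[rep_tbl$is_contaminant])
  expect_length(intersect(removed, never_in_controls), 0)
})

test_that("relative abundances are proportions summing to one", {
  one <- tibble::tibble(asv_id = c("a", "b"), s1 = c(4L, 0L))
  expect_equal(transform_relative_abundance(one)$s1, c(1, 0))

  counts <- tibble::tibble(asv_id = c("a", "b", "c"), s1 = c(1L, 2L, 3L))
  expect_equal(transform_relative_abundance(counts)$s1, c(1, 2, 3) / 6)

  sim_counts <- simulate_microcosm(simulation_config(
    seed = 3, n_soil_taxa = 30, n_snow_taxa = 15, n_shared_taxa = 5,
    n_planted = 3, reads_per_sample = 300
  ))$counts
  rel <- transform_relative_abundance(sim_counts)
  expect_true(all(abs(colSums(as.matrix(rel[-1])) - 1) < 1e-9))

  zero <- tibble::tibble(asv_id = "a", bad = 0L, ok = 2L)
  expect_error(transform_relative_abundance(zero), "bad")
})

test_that("rarefaction expectation matches closed form and Monte Carlo", {
  counts <- c(5, 3, 2)
  expect_equal(rarefaction_curve(counts, 10)$expected_richness, 3)
  expect_equal(rarefaction_curve(counts, 1)$expected_richness, 1)
  expect_equal(rarefaction_curve(counts, 2)$expected_richness,
               3 - (choose(5, 2) + choose(7, 2) + choose(8, 2)) /
                 choose(10, 2))  # 1.6889

  curve <- rarefaction_curve(counts, 1:10)
  expect_true(all(diff(curve$expected_richness) >= -1e-12))
  expect_error(rarefaction_curve(counts, 11), "depth")

  # Monte-Carlo oracle: subsample reads without replacement
  set.seed(99)
  toy <- c(12, 6, 3, 1, 1)
  pool <- rep(seq_along(toy), toy)
  draws <- replicate(10000, length(unique(sample(pool, 7))))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(
    abs(rarefaction_curve(toy, 7)$expected_richness - mean(draws)),
    3 * se
  )
})
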