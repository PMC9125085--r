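#' Status levels of the colonisation classification chain
#'
#' Snow-derived ASVs move along a nested chain: `excluded` (seen in snow but
#' also in control microcosms or pre-treatment soils), `candidate` (snow
#' ASV surviving the exclusion, not yet seen in treated soil), `invader`
#' (candidate detected in treated soil on at least one post-start day),
#' `potential_colonist` (invader detected on multiple distinct days,
#' replicates pooled), and `successful_colonist` (potential colonist still
#' detected on the final sampling day).
#'
#' @return Character vector of the five status labels in chain order.
#' @export
colonisation_statuses <- function() {
  c("excluded", "candidate", "invader", "potential_colonist",
    "successful_colonist")
}

#' Candidate pool of snow-derived ASVs
#'
#' Applies the exclusion step of the colonisation analysis: starting from all
#' ASVs identified in at least one snow sample, discard every ASV identified
#' in any control-microcosm sample (any day) or in any pre-treatment soil
#' sample (days DS, D-10 and D0, treatment and control arms alike). What
#' remains is the pool of snow-derived candidates whose fate in the treated
#' soils is then classified.
#'
#' @param detection A detection tibble from [detection_table()].
#' @param include_control_ft Should flow-through samples of control
#'   microcosms count towards the exclusion set (default `TRUE`), or only
#'   control soils? The narrower reading is exposed because "identified in
#'   the control microcosms" is ambiguous about compartments.
#' @return Character vector of candidate ASV identifiers.
#' @export
candidate_pool <- function(detection, include_control_ft = TRUE) {
  if (!any(detection$compartment == "snow")) {
    stop("no snow samples in the dataset; cannot form a candidate pool",
         call. = FALSE)
  }
  det <- dplyr::filter(detection, .data$detected)
  snow_asvs <- unique(det$asv_id[det$compartment == "snow"])
  control_comps <- if (include_control_ft) {
    c("soil", "flow_through")
  } else {
    "soil"
  }
  in_controls <- unique(det$asv_id[
    det$arm %in% "control" & det$compartment %in% control_comps
  ])
  pre_soil <- unique(det$asv_id[
    det$compartment == "soil" &
      as.character(det$day) %in% pre_treatment_days()
  ])
  setdiff(snow_asvs, union(in_controls, pre_soil))
}

#' Classify snow-derived ASVs as invaders and colonists
#'
#' Runs the full classification chain per experimental unit (each treatment
#' condition: e.g. average, fast, acidic, alkaline), pooling detections over
#' replicates. An ASV in the candidate pool becomes an `invader` of a unit
#' when detected in that unit's treated soil on at least one post-start day
#' (D5 onward); a `potential_colonist` when detected on at least `min_days`
#' distinct post-start days — gaps between detections are allowed, since
#' taxa can fall below the detection threshold and reappear; and a
#' `successful_colonist` when additionally detected on `final_day` in any
#' replicate. Abundance trends play no role. The pool is computed
#' dataset-wide, so the same ASV can be a colonist of several units.
#'
#' @inheritParams candidate_pool
#' @param pool Optional precomputed candidate pool; defaults to
#'   [candidate_pool()] on `detection`.
#' @param final_day Final sampling day label (default `"D29"`).
#' @param min_days Minimum number of distinct post-start detection days for
#'   a potential colonist (default 2).
#' @return A tibble of class `mc_colonisation` with one row per
#'   (snow-derived ASV, unit): `asv_id`, `experiment`, `condition`, `status`
#'   (ordered factor over [colonisation_statuses()]), `detection_days`
#'   (comma-separated), `n_detection_days`, `detected_on_final_day`.
#' @export
classify_colonists <- function(detection, pool = NULL, final_day = "D29",
                               min_days = 2, include_control_ft = TRUE) {
  if (!final_day %in% post_start_days()) {
    stop("final_day must be a post-start day label", call. = FALSE)
  }
  if (is.null(pool)) {
    pool <- candidate_pool(detection, include_control_ft)
  }
  snow_asvs <- unique(detection$asv_id[
    detection$detected & detection$compartment == "snow"
  ])
  units <- detection %>%
    dplyr::filter(.data$compartment == "soil", .data$arm == "treatment",
                  as.character(.data$day) %in% post_start_days()) %>%
    dplyr::distinct(.data$experiment, .data$condition, .data$day) %>%
    dplyr::count(.data$experiment, .data$condition, name = "n_days_sampled")
  if (nrow(units) == 0) {
    stop("no treated-soil samples on post-start days", call. = FALSE)
  }
  if (any(units$n_days_sampled < 2)) {
    bad <- units$condition[units$n_days_sampled < 2]
    stop("unit(s) sampled on fewer than two post-start days: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  hits <- detection %>%
    dplyr::filter(.data$detected, .data$compartment == "soil",
                  .data$arm == "treatment",
                  as.character(.data$day) %in% post_start_days(),
                  .data$asv_id %in% pool) %>%
    dplyr::distinct(.data$asv_id, .data$experiment, .data$condition,
                    day = as.character(.data$day)) %>%
    dplyr::group_by(.data$asv_id, .data$experiment, .data$condition) %>%
    dplyr::summarise(
      detection_days = paste(sort_days(unique(.data$day)), collapse = ","),
      n_detection_days = dplyr::n_distinct(.data$day),
      detected_on_final_day = final_day %in% .data$day,
      .groups = "drop"
    )

  grid <- tidyr::expand_grid(
    asv_id = snow_asvs,
    units[, c("experiment", "condition")]
  )
  calls <- grid %>%
    dplyr::left_join(hits, by = c("asv_id", "experiment", "condition")) %>%
    dplyr::mutate(
      detection_days = dplyr::coalesce(.data$detection_days, ""),
      n_detection_days = dplyr::coalesce(.data$n_detection_days, 0L),
      detected_on_final_day = dplyr::coalesce(.data$detected_on_final_day,
                                              FALSE),
      status = call_status(.data$asv_id %in% pool, .data$n_detection_days,
                           .data$detected_on_final_day, min_days)
    ) %>%
    dplyr::arrange(.data$experiment, .data$condition,
                   dplyr::desc(.data$status), .data$asv_id)
  class(calls) <- c("mc_colonisation", class(calls))
  attr(calls, "pool") <- pool
  attr(calls, "params") <- list(final_day = final_day, min_days = min_days,
                                include_control_ft = include_control_ft)
  calls
}

call_status <- function(in_pool, n_days, on_final, min_days) {
  status <- rep("excluded", length(in_pool))
  status[in_pool] <- "candidate"
  status[in_pool & n_days >= 1] <- "invader"
  status[in_pool & n_days >= min_days] <- "potential_colonist"
  status[in_pool & n_days >= min_days & on_final] <- "successful_colonist"
  factor(status, levels = colonisation_statuses(), ordered = TRUE)
}

sort_days <- function(days) {
  days[order(match(days, day_levels()))]
}

#' Per-unit colonisation counts
#'
#' Summarises classification calls into the headline counts: per experimental
#' unit, how many ASVs reached at least invader, potential-colonist and
#' successful-colonist status. Counts are cumulative along the chain, so
#' `invaders >= colonists >= successful` always holds.
#'
#' @param calls A call tibble from [classify_colonists()].
#' @return A tibble with columns `experiment`, `condition`, `invaders`,
#'   `colonists`, `successful`.
#' @export
summarize_colonisation <- function(calls) {
  calls %>%
    dplyr::group_by(.data$experiment, .data$condition) %>%
    dplyr::summarise(
      invaders = sum(.data$status >= "invader"),
      colonists = sum(.data$status >= "potential_colonist"),
      successful = sum(.data$status >= "successful_colonist"),
      .groups = "drop"
    )
}

#' Dataset-wide colonisation overview
#'
#' The global accounting of the exclusion chain: the candidate-pool size
#' (snow-derived ASVs surviving exclusion), the number of distinct ASVs that
#' invaded at least one unit, and the remainder — snow-unique ASVs never
#' detected in treated soil. By construction
#' `pool_size = global_invaders + noninvading_snow_unique`, the identity
#' [non_invading_pool()] expresses directly.
#'
#' @inheritParams summarize_colonisation
#' @return A one-row tibble with `pool_size`, `global_invaders` and
#'   `noninvading_snow_unique`.
#' @export
colonisation_overview <- function(calls) {
  pool <- attr(calls, "pool")
  pool_size <- if (!is.null(pool)) length(pool) else {
    dplyr::n_distinct(calls$asv_id[calls$status >= "candidate"])
  }
  global_invaders <- dplyr::n_distinct(
    calls$asv_id[calls$status >= "invader"]
  )
  tibble::tibble(
    pool_size = pool_size,
    global_invaders = global_invaders,
    noninvading_snow_unique = non_invading_pool(pool_size, global_invaders)
  )
}

#' Non-invading remainder of the candidate pool
#'
#' Snow-derived candidate ASVs that never appeared in treated soil: the pool
#' size minus the number of distinct invaders.
#'
#' @param pool_size Size of the candidate pool.
#' @param n_invaders Number of distinct invading ASVs.
#' @return `pool_size - n_invaders`.
#' @export
#' @examples
#' non_invading_pool(541, 16)  # 525
non_invading_pool <- function(pool_size, n_invaders) {
  if (n_invaders > pool_size) {
    stop("invaders cannot exceed the pool size", call. = FALSE)
  }
  pool_size - n_invaders
}

#' Per-replicate colonisation counts
#'
#' Re-applies the invader/colonist/successful definitions within each
#' replicate microcosm separately (no pooling over replicates) and counts
#' ASVs per status, giving the replicate-level response on which differences
#' between experimental units can be tested by ANOVA.
#'
#' @inheritParams classify_colonists
#' @return A tibble with one row per (experiment, condition, replicate):
#'   `invaders`, `colonists`, `successful`.
#' @export
replicate_colonist_counts <- function(detection, pool = NULL,
                                      final_day = "D29", min_days = 2,
                                      include_control_ft = TRUE) {
  if (is.null(pool)) {
    pool <- candidate_pool(detection, include_control_ft)
  }
  reps <- detection %>%
    dplyr::filter(.data$compartment == "soil", .data$arm == "treatment",
                  as.character(.data$day) %in% post_start_days()) %>%
    dplyr::distinct(.data$experiment, .data$condition, .data$replicate)
  if (nrow(reps) == 0) {
    stop("no treated-soil samples on post-start days", call. = FALSE)
  }
  hits <- detection %>%
    dplyr::filter(.data$detected, .data$compartment == "soil",
                  .data$arm == "treatment",
                  as.character(.data$day) %in% post_start_days(),
                  .data$asv_id %in% pool) %>%
    dplyr::distinct(.data$asv_id, .data$experiment, .data$condition,
                    .data$replicate, day = as.character(.data$day)) %>%
    dplyr::group_by(.data$asv_id, .data$experiment, .data$condition,
                    .data$replicate) %>%
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$day),
      on_final = final_day %in% .data$day,
      .groups = "drop"
    )
  hits %>%
    dplyr::group_by(.data$experiment, .data$condition, .data$replicate) %>%
    dplyr::summarise(
      invaders = sum(.data$n_days >= 1),
      colonists = sum(.data$n_days >= min_days),
      successful = sum(.data$n_days >= min_days & .data$on_final),
      .groups = "drop"
    ) %>%
    dplyr::right_join(reps,
                      by = c("experiment", "condition", "replicate")) %>%
    dplyr::mutate(dplyr::across(c("invaders", "colonists", "successful"),
                                ~ dplyr::coalesce(.x, 0L))) %>%
    dplyr::arrange(.data$experiment, .data$condition, .data$replicate)
}

#' ANOVA on per-replicate colonisation counts
#'
#' Tests whether the number of invaders, colonists and successful colonists
#' per replicate differs between experimental units, by one-way sequential
#' ANOVA on the per-replicate counts (see [replicate_colonist_counts()]).
#'
#' @param rep_counts Output of [replicate_colonist_counts()].
#' @return A tibble with one row per category: `category`, `df`, `df_resid`,
#'   `statistic`, `p_value`.
#' @export
colonist_counts_anova <- function(rep_counts) {
  if (dplyr::n_distinct(rep_counts$condition) < 2) {
    stop("need at least two experimental units", call. = FALSE)
  }
  if (any(table(rep_counts$condition) < 2)) {
    stop("need at least two replicates per unit", call. = FALSE)
  }
  purrr::map_dfr(c("invaders", "colonists", "successful"), function(cat) {
    dat <- data.frame(y = rep_counts[[cat]],
                      condition = factor(rep_counts$condition))
    if (stats::var(dat$y) == 0) {
      # constant response: no variation to partition
      return(tibble::tibble(
        category = cat, df = nlevels(dat$condition) - 1,
        df_resid = nrow(dat) - nlevels(dat$condition),
        statistic = 0, p_value = 1
      ))
    }
    tab <- anova_sequential(dat, y ~ condition)
    tibble::tibble(
      category = cat,
      df = tab$df[1],
      df_resid = tab$df[2],
      statistic = tab$statistic[1],
      p_value = tab$p_value[1]
    )
  })
}

#' Long-format invader abundance table for heatmaps
#'
#' One row per invader ASV x replicate x post-start day within each unit,
#' carrying the ASV's relative abundance in that treated-soil sample
#' (zero-filled where undetected) and its classification status — the tidy
#' data behind an invader heatmap.
#'
#' @inheritParams summarize_colonisation
#' @param relabund Relative-abundance tibble from
#'   [transform_relative_abundance()].
#' @param metadata Validated sample metadata.
#' @return A tibble with columns `asv_id`, `experiment`, `condition`,
#'   `replicate`, `day`, `relative_abundance`, `status`.
#' @export
heatmap_table <- function(calls, relabund, metadata) {
  metadata <- validate_metadata(metadata)
  invaders <- calls %>% dplyr::filter(.data$status >= "invader")
  empty <- tibble::tibble(
    asv_id = character(), experiment = character(), condition = character(),
    replicate = integer(), day = character(), relative_abundance = double(),
    status = factor(character(), levels = colonisation_statuses(),
                    ordered = TRUE)
  )
  if (nrow(invaders) == 0) return(empty)
  soil <- metadata %>%
    dplyr::filter(.data$compartment == "soil", .data$arm == "treatment",
                  as.character(.data$day) %in% post_start_days())
  long_ra <- relabund %>%
    tidyr::pivot_longer(-"asv_id", names_to = "sample_id",
                        values_to = "relative_abundance") %>%
    dplyr::inner_join(soil, by = "sample_id")
  grid <- invaders %>%
    dplyr::select("asv_id", "experiment", "condition", "status") %>%
    dplyr::inner_join(
      soil %>%
        dplyr::distinct(.data$experiment, .data$condition, .data$replicate,
                        day = as.character(.data$day)),
      by = c("experiment", "condition"),
      relationship = "many-to-many"
    )
  grid %>%
    dplyr::left_join(
      long_ra %>%
        dplyr::mutate(day = as.character(.data$day)) %>%
        dplyr::select("asv_id", "experiment", "condition", "replicate",
                      "day", "relative_abundance"),
      by = c("asv_id", "experiment", "condition", "replicate", "day")
    ) %>%
    dplyr::mutate(
      relative_abundance = dplyr::coalesce(.data$relative_abundance, 0)
    ) %>%
    dplyr::arrange(.data$experiment, .data$condition, .data$asv_id,
                   .data$replicate, match(.data$day, day_levels()))
}
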