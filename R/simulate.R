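#' Configuration for the microcosm community simulator
#'
#' Assembles and validates the parameters of [simulate_microcosm()]. The
#' defaults mirror the study design the analysis targets: two experiment
#' sets (melt rate with average and fast conditions; soil pH with acidic and
#' alkaline conditions), treatment and control arms in triplicate (12
#' microcosms per experiment), the DS/D-10/D0/D5/D9/D14/D20/D29 sampling
#' schedule, a fixed sequencing depth of 30,114 reads per sample, and a mean
#' of 40.2 16S gene copies per ml of melted snow with soil and flow-through
#' compartments orders of magnitude higher.
#'
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @param replicates Replicate microcosms per arm (default 3).
#' @param reads_per_sample Sequencing depth; every sample's counts sum to
#'   exactly this (default 30114).
#' @param n_soil_taxa,n_snow_taxa,n_shared_taxa Background community sizes:
#'   soil-only, snow-only and shared (snow-and-soil) taxa.
#' @param n_contaminant_taxa Reagent-contaminant taxa planted in the
#'   laboratory controls.
#' @param n_planted Snow taxa planted as invaders of treated soils
#'   (default 20); they are drawn from the snow-only set and never appear in
#'   control microcosms or pre-treatment soils.
#' @param planted_per_condition Optional named integer vector giving how many
#'   of the planted taxa arrive in each condition (names among the condition
#'   labels); defaults to all planted taxa in every condition.
#' @param planted_base_relabund Latent relative abundance of a planted taxon
#'   in treated soil (default 1e-3, comfortably above the detection limit at
#'   the default depth).
#' @param arrival_day First sampled day a planted taxon is present in
#'   treated soil (default `"D5"`).
#' @param survival_prob Probability that a planted taxon still present at one
#'   sampled day persists to the next sampled day, per replicate (default 1).
#'   Lower values emulate washout under fast flow.
#' @param abundance_multiplier Per-sampling-day multiplier on a planted
#'   taxon's latent abundance after arrival (default 1).
#' @param detection_probability Probability that a latently present planted
#'   taxon is carried into the sampled community of a given treated-soil
#'   sample (default 1).
#' @param abundance_sdlog Log-normal sdlog of background taxon abundances
#'   (rank-abundance shape; default 1.5).
#' @param qpcr_mean_copies Named vector of mean gene copies per unit for
#'   `snow` (per ml), `soil` (per g) and `flow_through` (per ml).
#' @param qpcr_sdlog Log-scale noise of the qPCR generator (default 0.3).
#' @param ft_day5_spike Multiplier on flow-through gene copies on D5,
#'   emulating the washout of relic DNA and unattached cells (default 5).
#' @return A list of class `mc_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              replicates = 3,
                              reads_per_sample = 30114,
                              n_soil_taxa = 300,
                              n_snow_taxa = 120,
                              n_shared_taxa = 30,
                              n_contaminant_taxa = 5,
                              n_planted = 20,
                              planted_per_condition = NULL,
                              planted_base_relabund = 1e-3,
                              arrival_day = "D5",
                              survival_prob = 1,
                              abundance_multiplier = 1,
                              detection_probability = 1,
                              abundance_sdlog = 1.5,
                              qpcr_mean_copies = c(snow = 40.2,
                                                   soil = 1e7,
                                                   flow_through = 1e4),
                              qpcr_sdlog = 0.3,
                              ft_day5_spike = 5) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (reads_per_sample < 1) {
    stop("reads_per_sample must be >= 1", call. = FALSE)
  }
  if (n_planted > n_snow_taxa) {
    stop("planted taxa cannot exceed the snow-only taxon budget",
         call. = FALSE)
  }
  if (detection_probability <= 0 || detection_probability > 1) {
    stop("detection_probability must be in (0, 1]", call. = FALSE)
  }
  if (survival_prob <= 0 || survival_prob > 1) {
    stop("survival_prob must be in (0, 1]", call. = FALSE)
  }
  if (!arrival_day %in% post_start_days()) {
    stop("arrival_day must be one of: ",
         paste(post_start_days(), collapse = ", "), call. = FALSE)
  }
  units <- tibble::tibble(
    experiment = c("melt_rate", "melt_rate", "soil_ph", "soil_ph"),
    condition = c("average", "fast", "acidic", "alkaline")
  )
  if (!is.null(planted_per_condition)) {
    bad <- setdiff(names(planted_per_condition), units$condition)
    if (length(bad) > 0) {
      stop("planted_per_condition names not among conditions: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(planted_per_condition > n_planted)) {
      stop("planted_per_condition cannot exceed n_planted", call. = FALSE)
    }
  }
  structure(
    list(seed = seed, replicates = replicates,
         reads_per_sample = reads_per_sample,
         n_soil_taxa = n_soil_taxa, n_snow_taxa = n_snow_taxa,
         n_shared_taxa = n_shared_taxa,
         n_contaminant_taxa = n_contaminant_taxa,
         n_planted = n_planted,
         planted_per_condition = planted_per_condition,
         planted_base_relabund = planted_base_relabund,
         arrival_day = arrival_day, survival_prob = survival_prob,
         abundance_multiplier = abundance_multiplier,
         detection_probability = detection_probability,
         abundance_sdlog = abundance_sdlog,
         qpcr_mean_copies = qpcr_mean_copies, qpcr_sdlog = qpcr_sdlog,
         ft_day5_spike = ft_day5_spike, units = units),
    class = "mc_sim_config"
  )
}

#' Simulate a ground-truthed microcosm dataset
#'
#' Generates an ASV count table, sample metadata, per-taxon ground truth and
#' qPCR quantities with the statistical structure the colonisation analysis
#' assumes. Background communities per compartment have log-normal
#' rank-abundance shapes and are compositionally stable across days (small
#' multiplicative per-sample jitter). Planted snow taxa appear in treated
#' soils from their arrival day, persist between sampled days with the
#' configured survival probability per replicate, and never occur in control
#' microcosms or pre-treatment soils in the latent state — multinomial read
#' sampling can only remove detections, never add them, so the observed data
#' obey the same constraint. Flow-through samples mix washed-out soil taxa
#' with snow input (treatment arms only); laboratory controls carry the
#' contaminant taxa at elevated relative abundance, with sporadic low-level
#' carry-over into true samples.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mc_simulation` with elements `counts` (count
#'   tibble), `metadata` (validated tibble), `truth` (tibble: `asv_id`,
#'   `origin`, and per-unit planted status columns via `experiment`,
#'   `condition`, `planted_status`), `qpcr` (tibble accepted by
#'   [qpcr_copies_per_unit()]) and `config`.
#' @export
simulate_microcosm <- function(config = simulation_config()) {
  stopifnot(inherits(config, "mc_sim_config"))
  withr::with_seed(config$seed, simulate_microcosm_impl(config))
}

simulate_microcosm_impl <- function(config) {
  units <- config$units
  reps <- seq_len(config$replicates)
  soil_days <- c("D0", post_start_days())
  ft_days <- c("D5", "D9", "D14")
  snow_days <- c("DS", "D-10", "D0", "D5", "D9", "D14")
  post_days <- post_start_days()

  taxa <- tibble::tibble(
    asv_id = c(
      sprintf("soil_%03d", seq_len(config$n_soil_taxa)),
      sprintf("snow_%03d", seq_len(config$n_snow_taxa)),
      sprintf("shared_%03d", seq_len(config$n_shared_taxa)),
      sprintf("contam_%02d", seq_len(config$n_contaminant_taxa))
    ),
    origin = rep(c("soil", "snow", "shared", "contaminant"),
                 c(config$n_soil_taxa, config$n_snow_taxa,
                   config$n_shared_taxa, config$n_contaminant_taxa))
  )
  planted_ids <- taxa$asv_id[taxa$origin == "snow"][seq_len(config$n_planted)]

  # stable base communities; per-sample noise is multiplicative and small
  base_abund <- function(n) stats::rlnorm(n, 0, config$abundance_sdlog)
  soil_base <- base_abund(config$n_soil_taxa)
  snow_base <- base_abund(config$n_snow_taxa)
  shared_base <- base_abund(config$n_shared_taxa)
  contam_base <- base_abund(config$n_contaminant_taxa)
  is_soil <- taxa$origin == "soil"
  is_snow <- taxa$origin == "snow"
  is_shared <- taxa$origin == "shared"
  is_contam <- taxa$origin == "contaminant"
  n_taxa <- nrow(taxa)
  jitter <- function() stats::rlnorm(n_taxa, 0, 0.3)

  # which planted taxa arrive in which condition
  arrivals <- lapply(stats::setNames(units$condition, units$condition),
                     function(cond) {
    k <- config$n_planted
    if (!is.null(config$planted_per_condition) &&
        cond %in% names(config$planted_per_condition)) {
      k <- config$planted_per_condition[[cond]]
    }
    planted_ids[seq_len(k)]
  })

  # latent persistence per (condition, replicate, planted taxon):
  # alive at arrival_day, survives each subsequent sampled day with
  # survival_prob; once absent, stays absent
  arrival_idx <- match(config$arrival_day, post_days)
  latent <- list()
  for (u in seq_len(nrow(units))) {
    cond <- units$condition[u]
    for (r in reps) {
      alive <- matrix(FALSE, nrow = length(arrivals[[cond]]),
                      ncol = length(post_days),
                      dimnames = list(arrivals[[cond]], post_days))
      for (ti in seq_along(arrivals[[cond]])) {
        state <- TRUE
        for (di in seq(arrival_idx, length(post_days))) {
          if (di > arrival_idx) {
            state <- state && stats::runif(1) < config$survival_prob
          }
          alive[ti, di] <- state
        }
      }
      latent[[paste(cond, r, sep = "|")]] <- alive
    }
  }

  sample_rows <- list()
  count_cols <- list()
  qpcr_rows <- list()
  sid <- 0

  add_sample <- function(sample_id, compartment, experiment, arm, condition,
                         replicate, day, denom, relabund) {
    relabund <- relabund / sum(relabund)
    counts <- stats::rmultinom(1, config$reads_per_sample, relabund)[, 1]
    sample_rows[[length(sample_rows) + 1]] <<- tibble::tibble(
      sample_id = sample_id, compartment = compartment,
      experiment = experiment, arm = arm, condition = condition,
      replicate = replicate, day = day, denom = denom
    )
    count_cols[[sample_id]] <<- counts
    if (compartment != "lab_control") {
      mu <- config$qpcr_mean_copies[[compartment]]
      spike <- if (compartment == "flow_through" && identical(day, "D5")) {
        config$ft_day5_spike
      } else 1
      cpu <- stats::rlnorm(1, log(mu * spike), config$qpcr_sdlog)
      qpcr_rows[[length(qpcr_rows) + 1]] <<- tibble::tibble(
        sample_id = sample_id, compartment = compartment, day = day,
        copies_per_reaction = cpu * denom / (100 / 2),
        eluate_volume_ul = 100, template_volume_ul = 2, denom = denom
      )
    }
  }

  # sporadic contaminant carry-over into true samples
  contam_vec <- function() {
    v <- numeric(n_taxa)
    hit <- stats::runif(config$n_contaminant_taxa) < 0.05
    v[is_contam][hit] <- 1e-4 * contam_base[hit]
    v
  }

  snow_community <- function() {
    v <- numeric(n_taxa)
    v[is_snow] <- snow_base
    v[is_shared] <- shared_base
    (v * jitter() + contam_vec())
  }
  soil_community <- function() {
    v <- numeric(n_taxa)
    v[is_soil] <- soil_base
    v[is_shared] <- 0.2 * shared_base
    (v * jitter() + contam_vec())
  }

  # snow input samples (shared across experiments)
  for (day in snow_days) {
    sid <- sid + 1
    add_sample(sprintf("snow_%s", gsub("-", "m", day)), "snow", "melt_rate",
               "treatment", NA_character_, 1L, day, 250, snow_community())
  }
  # pre-treatment source soils per experiment (DS, D-10)
  for (ex in unique(units$experiment)) {
    cond0 <- units$condition[units$experiment == ex][1]
    for (day in c("DS", "D-10")) {
      add_sample(sprintf("soil_%s_%s", ex, gsub("-", "m", day)), "soil", ex,
                 "treatment", cond0, 1L, day, 0.25, soil_community())
    }
  }
  # microcosm soils and flow-through
  for (u in seq_len(nrow(units))) {
    ex <- units$experiment[u]
    cond <- units$condition[u]
    for (arm in c("treatment", "control")) {
      for (r in reps) {
        alive <- latent[[paste(cond, r, sep = "|")]]
        for (day in soil_days) {
          v <- soil_community()
          if (arm == "treatment" && day %in% post_days) {
            present <- rownames(alive)[alive[, day]]
            if (config$detection_probability < 1 && length(present) > 0) {
              keep <- stats::runif(length(present)) <
                config$detection_probability
              present <- present[keep]
            }
            di <- match(day, post_days)
            v[match(present, taxa$asv_id)] <-
              config$planted_base_relabund * sum(v) *
              config$abundance_multiplier^(di - arrival_idx)
          }
          add_sample(sprintf("%s_%s_%s_r%d_%s", ex, cond, substr(arm, 1, 4),
                             r, gsub("-", "m", day)),
                     "soil", ex, arm, cond, r, day, 0.25, v)
        }
        for (day in ft_days) {
          v <- soil_community()
          if (arm == "treatment") {
            v <- v + 0.3 * snow_community()
          }
          add_sample(sprintf("%s_%s_%s_r%d_ft_%s", ex, cond,
                             substr(arm, 1, 4), r, day),
                     "flow_through", ex, arm, cond, r, day, 250, v)
        }
      }
    }
  }
  # laboratory controls: contaminants dominate a sparse background
  for (ctrl in c("kit", "miseq")) {
    v <- numeric(n_taxa)
    v[is_contam] <- 50 * contam_base
    bg <- sample(which(is_soil), 5)
    v[bg] <- 0.05 * soil_base[bg]
    add_sample(paste0("labctrl_", ctrl), "lab_control", NA_character_,
               NA_character_, NA_character_, NA_integer_, NA_character_,
               NA_real_, v * stats::rlnorm(n_taxa, 0, 0.3))
  }

  metadata <- dplyr::bind_rows(sample_rows)
  counts <- dplyr::bind_cols(
    tibble::tibble(asv_id = taxa$asv_id),
    tibble::as_tibble(count_cols)
  )

  # ground truth from the pooled latent trajectories, per unit
  truth <- purrr::map_dfr(seq_len(nrow(units)), function(u) {
    cond <- units$condition[u]
    pooled <- Reduce(`|`, lapply(reps, function(r) {
      latent[[paste(cond, r, sep = "|")]]
    }))
    status <- apply(pooled, 1, function(row) {
      n_days <- sum(row)
      if (n_days == 0) return("none")
      if (n_days >= 2 && row[["D29"]]) return("successful_colonist")
      if (n_days >= 2) return("potential_colonist")
      "invader"
    })
    planted_tbl <- tibble::tibble(
      asv_id = rownames(pooled), planted_status = unname(status)
    )
    taxa %>%
      dplyr::left_join(planted_tbl, by = "asv_id") %>%
      dplyr::mutate(
        experiment = units$experiment[u], condition = cond,
        planted_status = dplyr::coalesce(.data$planted_status, "none")
      )
  })

  structure(
    list(counts = validate_counts(counts),
         metadata = validate_metadata(metadata),
         truth = truth,
         qpcr = dplyr::bind_rows(qpcr_rows),
         config = config),
    class = "mc_simulation"
  )
}

#' @export
print.mc_simulation <- function(x, ...) {
  cat("Simulated microcosm dataset:", nrow(x$counts), "taxa x",
      ncol(x$counts) - 1, "samples;", x$config$n_planted,
      "planted invader taxa; seed", x$config$seed, "\n")
  invisible(x)
}

#' Confusion summary of calls against planted ground truth
#'
#' Compares classification calls with the simulator's planted truth and
#' reports precision and recall per status, where each status is read
#' cumulatively along the chain (an ASV called successful also counts as
#' called invader and colonist, matching the nested definitions).
#'
#' @param calls Calls from [classify_colonists()].
#' @param truth Truth tibble from [simulate_microcosm()] (`$truth`).
#' @return A tibble with columns `status`, `n_truth`, `n_called`,
#'   `n_correct`, `precision`, `recall`. Precision is `NA` when nothing was
#'   called at that status; recall is `NA` when nothing was planted.
#' @export
truth_confusion <- function(calls, truth) {
  if (length(intersect(calls$asv_id, truth$asv_id)) == 0) {
    stop("calls and truth share no asv_id; namespace mismatch",
         call. = FALSE)
  }
  chain <- c("invader", "potential_colonist", "successful_colonist")
  key <- function(df) paste(df$asv_id, df$experiment, df$condition)
  purrr::map_dfr(chain, function(s) {
    truth_set <- key(truth[match_status_at_least(truth$planted_status, s), ])
    call_set <- key(calls[calls$status >= s, ])
    n_correct <- length(intersect(truth_set, call_set))
    tibble::tibble(
      status = s,
      n_truth = length(truth_set),
      n_called = length(call_set),
      n_correct = n_correct,
      precision = if (length(call_set) > 0) n_correct / length(call_set)
                  else NA_real_,
      recall = if (length(truth_set) > 0) n_correct / length(truth_set)
               else NA_real_
    )
  })
}

match_status_at_least <- function(status, s) {
  chain <- c("none", "invader", "potential_colonist", "successful_colonist")
  match(status, chain) >= match(s, chain)
}
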