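# Small in-code fixtures shared across test files.

# deterministic 3 ASV x 4 sample count table
tiny_counts <- function() {
  tibble::tibble(
    asv_id = c("asv1", "asv2", "asv3"),
    s1 = c(5L, 0L, 1L),
    s2 = c(0L, 3L, 2L),
    s3 = c(7L, 1L, 0L),
    s4 = c(2L, 2L, 2L)
  )
}

# hand-built colonisation fixture: eight ASVs with known fates in a single
# experimental unit (melt_rate / average) sampled on D5, D9 and D29 in two
# replicates, plus control soil, control flow-through and pre-treatment soil
toy_colonisation <- function() {
  metadata <- tibble::tibble(
    sample_id = c("snow1", "ctrl_soil", "ctrl_ft", "pre_soil",
                  "t_r1_d5", "t_r1_d9", "t_r1_d29", "t_r2_d5"),
    compartment = c("snow", "soil", "flow_through", "soil",
                    "soil", "soil", "soil", "soil"),
    experiment = "melt_rate",
    arm = c("treatment", "control", "control", "treatment",
            "treatment", "treatment", "treatment", "treatment"),
    condition = c(NA, "average", "average", "average",
                  "average", "average", "average", "average"),
    replicate = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L),
    day = c("D5", "D14", "D5", "D0", "D5", "D9", "D29", "D5")
  )
  rows <- list(
    # asv_id            snow ctrl ctrlft pre  r1d5 r1d9 r1d29 r2d5
    a_snow_only    = c(3, 0, 0, 0, 0, 0, 0, 0),  # candidate
    a_in_control   = c(3, 4, 0, 0, 2, 0, 0, 0),  # excluded (control soil)
    a_in_presoil   = c(3, 0, 0, 5, 0, 2, 0, 0),  # excluded (pre-treatment)
    a_one_day      = c(3, 0, 0, 0, 2, 0, 0, 0),  # invader (D5 only)
    a_all_days     = c(3, 0, 0, 0, 2, 2, 2, 0),  # successful (D5,D9,D29)
    a_gap          = c(3, 0, 0, 0, 2, 0, 2, 0),  # successful despite gap
    a_in_ctrl_ft   = c(3, 0, 6, 0, 2, 2, 0, 0),  # excluded iff FT counted
    soil_backgrnd  = c(0, 9, 9, 9, 9, 9, 9, 9)   # never snow: not called
  )
  counts <- dplyr::bind_cols(
    tibble::tibble(asv_id = names(rows)),
    tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal") |>
      rlang::set_names(metadata$sample_id)
  )
  list(counts = counts, metadata = metadata)
}

# brute-force set-algebra oracle for the exclusion -> classification chain,
# written with plain loops over samples, independent of the implementation
oracle_classify <- function(counts, metadata, threshold = 1,
                            include_control_ft = TRUE, min_days = 2,
                            final_day = "D29", by_replicate = FALSE) {
  post <- c("D5", "D9", "D14", "D20", "D29")
  pre <- c("DS", "D-10", "D0")
  detected <- function(asv, sample) {
    counts[[sample]][counts$asv_id == asv] >= threshold
  }
  snow_set <- control_set <- pre_set <- character(0)
  for (asv in counts$asv_id) {
    for (i in seq_len(nrow(metadata))) {
      s <- metadata$sample_id[i]
      if (!detected(asv, s)) next
      if (metadata$compartment[i] == "snow") snow_set <- union(snow_set, asv)
      comps <- if (include_control_ft) c("soil", "flow_through") else "soil"
      if (!is.na(metadata$arm[i]) && metadata$arm[i] == "control" &&
          metadata$compartment[i] %in% comps) {
        control_set <- union(control_set, asv)
      }
      if (metadata$compartment[i] == "soil" &&
          as.character(metadata$day[i]) %in% pre) {
        pre_set <- union(pre_set, asv)
      }
    }
  }
  pool <- setdiff(snow_set, union(control_set, pre_set))
  units <- unique(metadata[
    metadata$compartment == "soil" & metadata$arm %in% "treatment" &
      as.character(metadata$day) %in% post,
    c("experiment", "condition", "replicate")
  ])
  if (!by_replicate) units$replicate <- NULL
  units <- unique(units)
  out <- list()
  for (u in seq_len(nrow(units))) {
    for (asv in pool) {
      days <- character(0)
      for (i in seq_len(nrow(metadata))) {
        if (metadata$compartment[i] != "soil") next
        if (!metadata$arm[i] %in% "treatment") next
        if (!as.character(metadata$day[i]) %in% post) next
        if (metadata$experiment[i] != units$experiment[u]) next
        if (metadata$condition[i] != units$condition[u]) next
        if (by_replicate && metadata$replicate[i] != units$replicate[u]) next
        if (detected(asv, metadata$sample_id[i])) {
          days <- union(days, as.character(metadata$day[i]))
        }
      }
      status <- if (length(days) == 0) {
        "candidate"
      } else if (length(days) < min_days) {
        "invader"
      } else if (final_day %in% days) {
        "successful_colonist"
      } else {
        "potential_colonist"
      }
      out[[length(out) + 1]] <- tibble::tibble(
        asv_id = asv,
        experiment = units$experiment[u],
        condition = units$condition[u],
        replicate = if (by_replicate) units$replicate[u] else NA_integer_,
        status = status
      )
    }
  }
  list(pool = pool, calls = dplyr::bind_rows(out))
}
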