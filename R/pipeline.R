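#' Run the full colonisation analysis pipeline
#'
#' Executes the stages of the microcosm analysis in fixed order on a count
#' table and its metadata: control-abundance curation, prevalence-based
#' contaminant removal, relative-abundance normalisation, alpha diversity,
#' Bray-Curtis ordination and PERMANOVA, then the colonisation
#' classification chain with its summaries. Contaminant removal precedes all
#' downstream stages. Every stage's parameters are recorded in a run
#' manifest, and identical inputs plus an identical seed reproduce identical
#' outputs.
#'
#' @param counts Count tibble (see [validate_counts()]).
#' @param metadata Sample metadata (see [validate_metadata()]).
#' @param qpcr Optional qPCR table for [qpcr_copies_per_unit()].
#' @param threshold Detection threshold in reads (default 1).
#' @param score_threshold Contaminant score threshold (default 0.1).
#' @param min_days,final_day,include_control_ft Classification parameters,
#'   see [classify_colonists()].
#' @param permanova_formula Right-hand-side formula over metadata columns
#'   for the community-composition PERMANOVA on treated-soil samples
#'   (default `~ condition`), or `NULL` to skip.
#' @param n_permutations Permutations for the PERMANOVA (default 999).
#' @param seed Integer seed for all permutation procedures.
#' @return A list of class `mc_pipeline` with elements `curation`,
#'   `contaminants`, `counts_clean`, `relabund`, `alpha`, `distance`,
#'   `ordination`, `permanova`, `calls`, `unit_counts`, `overview`,
#'   `replicate_counts`, `counts_anova`, `heatmap`, `qpcr` (or `NULL`) and
#'   `manifest`.
#' @export
run_microcosm_pipeline <- function(counts, metadata, qpcr = NULL,
                                   threshold = 1, score_threshold = 0.1,
                                   min_days = 2, final_day = "D29",
                                   include_control_ft = TRUE,
                                   permanova_formula = ~condition,
                                   n_permutations = 999, seed = 1) {
  t0 <- Sys.time()
  counts <- validate_counts(counts)
  metadata <- validate_metadata(metadata)
  lab_ids <- metadata$sample_id[metadata$compartment == "lab_control"]
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
  }

  # 1. curation + contaminant identification against the lab controls
  if (length(lab_ids) > 0) {
    curation <- curate_control_abundance(counts, lab_ids)
    contaminants <- filter_contaminants_prevalence(
      curation$retained, negative_ids = lab_ids,
      score_threshold = score_threshold, threshold = threshold
    )
    keep <- contaminants$asv_id[!contaminants$is_contaminant]
    counts_clean <- curation$retained[
      curation$retained$asv_id %in% keep, , drop = FALSE
    ]
    # lab controls have served their purpose; drop them from analysis
    counts_clean <- counts_clean[
      , c("asv_id", setdiff(names(counts_clean),
                            c("asv_id", lab_ids))), drop = FALSE
    ]
  } else {
    curation <- list(retained = counts, discarded = character(0))
    contaminants <- NULL
    counts_clean <- counts
  }
  # drop taxa emptied by sample removal
  m <- as.matrix(counts_clean[, -1, drop = FALSE])
  counts_clean <- counts_clean[rowSums(m) > 0, , drop = FALSE]
  metadata_clean <- metadata[
    metadata$sample_id %in% names(counts_clean), , drop = FALSE
  ]
  tick("preprocess")

  # 2. community statistics
  relabund <- transform_relative_abundance(counts_clean)
  alpha <- alpha_diversity(counts_clean) %>%
    dplyr::left_join(metadata_clean, by = "sample_id")
  soil_ids <- metadata_clean$sample_id[
    metadata_clean$compartment == "soil" &
      metadata_clean$arm %in% "treatment"
  ]
  distance <- bray_curtis(relabund[, c("asv_id", soil_ids), drop = FALSE])
  ordination <- pcoa_ordination(distance)
  perm <- NULL
  if (!is.null(permanova_formula)) {
    soil_md <- metadata_clean[match(soil_ids, metadata_clean$sample_id), ]
    perm <- permanova(distance, soil_md, permanova_formula,
                      n_permutations = n_permutations, seed = seed)
  }
  tick("community_stats")

  # 3. colonisation classification
  detection <- detection_table(counts_clean, metadata_clean, threshold)
  pool <- candidate_pool(detection, include_control_ft)
  calls <- classify_colonists(detection, pool = pool, final_day = final_day,
                              min_days = min_days,
                              include_control_ft = include_control_ft)
  unit_counts <- summarize_colonisation(calls)
  overview <- colonisation_overview(calls)
  rep_counts <- replicate_colonist_counts(
    detection, pool = pool, final_day = final_day, min_days = min_days,
    include_control_ft = include_control_ft
  )
  counts_anova <- tryCatch(colonist_counts_anova(rep_counts),
                           error = function(e) NULL)
  heatmap <- heatmap_table(calls, relabund, metadata_clean)
  tick("colonisation")

  qpcr_out <- if (!is.null(qpcr)) qpcr_copies_per_unit(qpcr) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("microcolonize")),
    seed = seed,
    params = list(threshold = threshold, score_threshold = score_threshold,
                  min_days = min_days, final_day = final_day,
                  include_control_ft = include_control_ft,
                  n_permutations = n_permutations,
                  permanova_formula = if (!is.null(permanova_formula)) {
                    deparse(permanova_formula)
                  } else NA_character_),
    n_input_asvs = nrow(counts),
    n_input_samples = ncol(counts) - 1,
    n_curated_out = length(curation$discarded),
    n_contaminants = if (!is.null(contaminants)) {
      sum(contaminants$is_contaminant)
    } else 0L,
    n_clean_asvs = nrow(counts_clean),
    pool_size = length(pool),
    stage_seconds = timings
  )
  structure(
    list(curation = curation, contaminants = contaminants,
         counts_clean = counts_clean, relabund = relabund, alpha = alpha,
         distance = distance, ordination = ordination, permanova = perm,
         calls = calls, unit_counts = unit_counts, overview = overview,
         replicate_counts = rep_counts, counts_anova = counts_anova,
         heatmap = heatmap, qpcr = qpcr_out, manifest = manifest),
    class = "mc_pipeline"
  )
}

#' @export
print.mc_pipeline <- function(x, ...) {
  cat("Microcosm colonisation pipeline run\n")
  cat("  ASVs:", x$manifest$n_input_asvs, "in;",
      x$manifest$n_curated_out, "curated out;",
      x$manifest$n_contaminants, "contaminants;",
      x$manifest$n_clean_asvs, "retained\n")
  cat("  Candidate pool:", x$manifest$pool_size, "snow-derived ASVs\n")
  print(as.data.frame(x$unit_counts), row.names = FALSE)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Exports every tabular result of [run_microcosm_pipeline()] as a
#' tab-delimited file plus the run manifest as a key-value text file. The
#' manifest lists every file written.
#'
#' @param result An `mc_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "mc_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  put <- function(df, name) {
    if (is.null(df) || nrow(df) == 0 && ncol(df) == 0) return()
    path <- file.path(dir, paste0(name, ".tsv"))
    df <- dplyr::mutate(tibble::as_tibble(df),
                        dplyr::across(dplyr::where(is.factor), as.character))
    readr::write_tsv(df, path, progress = FALSE)
    written <<- c(written, basename(path))
  }
  put(result$contaminants, "contaminant_report")
  put(tibble::tibble(asv_id = result$curation$discarded), "curated_out")
  put(result$counts_clean, "counts_clean")
  put(result$relabund, "relative_abundance")
  put(result$alpha, "alpha_diversity")
  dm <- as.matrix(result$distance)
  put(tibble::as_tibble(dm, rownames = "sample_id"), "bray_curtis")
  put(tidy(result$ordination), "pcoa_coordinates")
  if (!is.null(result$permanova)) put(tidy(result$permanova), "permanova")
  put(tidy(result$calls), "colonisation_calls")
  put(result$unit_counts, "colonisation_counts")
  put(result$overview, "colonisation_overview")
  put(result$replicate_counts, "replicate_counts")
  if (!is.null(result$counts_anova)) put(result$counts_anova, "counts_anova")
  put(result$heatmap, "heatmap_table")
  if (!is.null(result$qpcr)) put(result$qpcr, "qpcr_normalised")

  mf <- result$manifest
  mf$files <- written
  fmt <- function(x) {
    paste(if (is.numeric(x)) format(x, trim = TRUE) else as.character(x),
          collapse = ",")
  }
  lines <- unlist(lapply(names(mf), function(k) {
    v <- mf[[k]]
    if (is.list(v)) {
      paste0(k, ".", names(v), "\t", vapply(v, fmt, character(1)))
    } else {
      paste0(k, "\t", fmt(v))
    }
  }))
  writeLines(lines, file.path(dir, "manifest.tsv"))
  invisible(c(written, "manifest.tsv"))
}
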