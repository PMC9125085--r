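#' Presence/absence detection from counts
#'
#' Converts a count table to detection calls: an ASV is "identified" in a
#' sample when its read count reaches the detection threshold. The default
#' threshold of one read equates identification with presence in the ASV
#' table; it is exposed because taxa can drop below the detection threshold
#' and reappear later in a time series.
#'
#' @param counts A count tibble (see [validate_counts()]).
#' @param threshold Minimum read count for a detection (integer >= 1).
#' @return A logical matrix (ASVs x samples) with ASV identifiers as row
#'   names. Raising the threshold never adds detections.
#' @export
presence_matrix <- function(counts, threshold = 1) {
  counts <- validate_counts(counts)
  if (threshold < 1) stop("threshold must be >= 1", call. = FALSE)
  m <- as.matrix(counts[, setdiff(names(counts), "asv_id"), drop = FALSE])
  rownames(m) <- counts$asv_id
  m >= threshold
}

#' Long-format detection table
#'
#' Tidy companion to [presence_matrix()]: one row per (ASV, sample) with a
#' logical `detected` column, joined to the sample metadata so downstream
#' classification can group by compartment, experiment, arm, condition,
#' replicate and day.
#'
#' @inheritParams presence_matrix
#' @param metadata A validated metadata tibble ([validate_metadata()]).
#' @return A tibble with columns `asv_id`, `sample_id`, `detected` and the
#'   metadata columns.
#' @export
detection_table <- function(counts, metadata, threshold = 1) {
  metadata <- validate_metadata(metadata)
  pm <- presence_matrix(counts, threshold)
  missing <- setdiff(colnames(pm), metadata$sample_id)
  if (length(missing) > 0) {
    stop("count table samples missing from metadata: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  long <- tibble::tibble(
    asv_id = rep(rownames(pm), times = ncol(pm)),
    sample_id = rep(colnames(pm), each = nrow(pm)),
    detected = as.vector(pm)
  )
  dplyr::left_join(long, metadata, by = "sample_id")
}

#' Prevalence-based contaminant identification
#'
#' Scores each ASV for enrichment in negative-control samples relative to
#' true samples, the prevalence logic used to flag reagent and sequencing
#' contaminants. For each ASV a 2x2 presence table (detected/not x
#' negative/true) is formed and scored with the one-sided exact
#' hypergeometric tail probability of seeing at least the observed number of
#' negative-control detections under random allocation. An ASV is called a
#' contaminant when the score falls below `score_threshold` and its
#' prevalence is strictly higher in negatives, or when it is detected only in
#' negatives.
#'
#' @inheritParams presence_matrix
#' @param negative_ids Character vector of negative-control sample
#'   identifiers (must be non-empty and leave at least one true sample).
#' @param score_threshold Classification threshold on the score
#'   (default 0.1).
#' @return A tibble with one row per ASV: `asv_id`,
#'   `prevalence_in_negatives`, `prevalence_in_samples`, `score`,
#'   `is_contaminant`.
#' @export
filter_contaminants_prevalence <- function(counts, negative_ids,
                                           score_threshold = 0.1,
                                           threshold = 1) {
  pm <- presence_matrix(counts, threshold)
  negative_ids <- as.character(negative_ids)
  if (length(negative_ids) == 0) {
    stop("at least one negative-control sample is required", call. = FALSE)
  }
  missing <- setdiff(negative_ids, colnames(pm))
  if (length(missing) > 0) {
    stop("negative sample(s) not in count table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  true_ids <- setdiff(colnames(pm), negative_ids)
  if (length(true_ids) == 0) {
    stop("all samples are negatives; at least one true sample is required",
         call. = FALSE)
  }
  n_neg <- length(negative_ids)
  n_true <- length(true_ids)
  k_neg <- unname(rowSums(pm[, negative_ids, drop = FALSE]))
  k_true <- unname(rowSums(pm[, true_ids, drop = FALSE]))
  score <- prevalence_score(k_neg, k_true, n_neg, n_true)
  prev_neg <- k_neg / n_neg
  prev_true <- k_true / n_true
  tibble::tibble(
    asv_id = rownames(pm),
    prevalence_in_negatives = prev_neg,
    prevalence_in_samples = prev_true,
    score = score,
    is_contaminant = (score < score_threshold & prev_neg > prev_true) |
      (k_neg > 0 & k_true == 0)
  )
}

#' Exact hypergeometric enrichment score
#'
#' One-sided tail probability P(X >= k_neg) for X hypergeometric: of the
#' `k_neg + k_true` samples in which the ASV is detected, how surprising is
#' it that `k_neg` fall among the `n_neg` negatives? Vectorised over ASVs.
#'
#' @param k_neg Detections among negatives.
#' @param k_true Detections among true samples.
#' @param n_neg Number of negative samples.
#' @param n_true Number of true samples.
#' @return Scores in \[0, 1\].
#' @export
prevalence_score <- function(k_neg, k_true, n_neg, n_true) {
  stats::phyper(k_neg - 1, m = k_neg + k_true,
                n = (n_neg + n_true) - (k_neg + k_true),
                k = n_neg, lower.tail = FALSE)
}

#' Control-abundance curation
#'
#' Discards ASVs present in the laboratory controls (extraction-kit and
#' sequencer blanks) at a higher mean relative abundance than in the
#' experimental samples. Mean relative abundance (rather than the maximum) is
#' used on each side so the comparison is robust to sequencing-depth
#' differences between controls and samples.
#'
#' @inheritParams presence_matrix
#' @param lab_control_ids Character vector of laboratory-control sample
#'   identifiers (non-empty).
#' @return A list with `retained` (the count tibble without discarded ASVs)
#'   and `discarded` (character vector of discarded ASV identifiers,
#'   possibly empty).
#' @export
curate_control_abundance <- function(counts, lab_control_ids) {
  counts <- validate_counts(counts)
  lab_control_ids <- as.character(lab_control_ids)
  if (length(lab_control_ids) == 0) {
    stop("lab_control_ids must be non-empty", call. = FALSE)
  }
  sample_cols <- setdiff(names(counts), "asv_id")
  missing <- setdiff(lab_control_ids, sample_cols)
  if (length(missing) > 0) {
    stop("lab control sample(s) not in count table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  other_ids <- setdiff(sample_cols, lab_control_ids)
  if (length(other_ids) == 0) {
    stop("no non-control samples to compare against", call. = FALSE)
  }
  m <- as.matrix(counts[, sample_cols, drop = FALSE])
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  mean_ctrl <- rowMeans(rel[, lab_control_ids, drop = FALSE])
  mean_other <- rowMeans(rel[, other_ids, drop = FALSE])
  discard <- counts$asv_id[mean_ctrl > mean_other]
  list(
    retained = counts[!counts$asv_id %in% discard, , drop = FALSE],
    discarded = discard
  )
}

#' Relative-abundance normalisation
#'
#' Divides each sample's counts by its total so every sample (column) sums
#' to one.
#'
#' @inheritParams presence_matrix
#' @return A tibble of the same shape as `counts` with proportions in place
#'   of counts.
#' @export
transform_relative_abundance <- function(counts) {
  counts <- validate_counts(counts)
  sample_cols <- setdiff(names(counts), "asv_id")
  m <- as.matrix(counts[, sample_cols, drop = FALSE])
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(sample_cols[totals == 0], collapse = ", "), call. = FALSE)
  }
  rel <- sweep(m, 2, totals, "/")
  out <- tibble::as_tibble(rel)
  dplyr::bind_cols(tibble::tibble(asv_id = counts$asv_id), out)
}

#' Expected rarefaction curve
#'
#' Expected number of taxa observed when a sample is rarefied (subsampled
#' without replacement) to each requested depth, computed in closed form from
#' the hypergeometric expectation
#' \deqn{E[S_d] = \sum_i \left(1 - \binom{N - N_i}{d} / \binom{N}{d}\right)}
#' with no resampling noise. The curve is non-decreasing in depth and reaches
#' the observed richness at full depth.
#'
#' @param sample_counts Non-negative integer vector of per-taxon counts for
#'   one sample.
#' @param depths Increasing vector of subsampling depths, each at most the
#'   sample's total count.
#' @return A tibble with columns `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(sample_counts, depths) {
  if (any(sample_counts < 0) || any(sample_counts != round(sample_counts))) {
    stop("sample_counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(sample_counts)
  if (any(depths > total)) {
    stop("depth exceeds total count (", total, ")", call. = FALSE)
  }
  if (any(depths < 1)) stop("depths must be >= 1", call. = FALSE)
  ni <- sample_counts[sample_counts > 0]
  expected <- vapply(depths, function(d) {
    # log-scale binomial ratios for numerical stability at sequencing depths
    sum(1 - exp(lchoose(total - ni, d) - lchoose(total, d)))
  }, numeric(1))
  tibble::tibble(depth = depths, expected_richness = expected)
}
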