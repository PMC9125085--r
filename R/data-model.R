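#' Sampling-day labels in experimental order
#'
#' The microcosm experiments are sampled on a fixed schedule: the day of field
#' sampling (`DS`), microcosm set-up (`D-10`), the first experimental day
#' (`D0`), and then days 5, 9, 14, 20 and 29 after the start of snow input.
#' Day labels are categorical, not numeric, so that `DS` and `D-10` sort
#' before `D0`; [day_offsets()] gives numeric positions for plotting.
#'
#' @return Character vector of the eight day labels in chronological order.
#' @export
#' @examples
#' day_levels()
day_levels <- function() {
  c("DS", "D-10", "D0", "D5", "D9", "D14", "D20", "D29")
}

#' @rdname day_levels
#' @details Numeric offsets place `DS` at -110 days (the soil was stored for
#'   roughly 100 days between field sampling and set-up) and `D-10` at -10;
#'   post-start labels carry their nominal day number.
#' @export
day_offsets <- function() {
  c("DS" = -110, "D-10" = -10, "D0" = 0, "D5" = 5, "D9" = 9,
    "D14" = 14, "D20" = 20, "D29" = 29)
}

#' @rdname day_levels
#' @details Post-start days are those on which a snow-derived ASV found in
#'   treated soil counts towards invasion: `D5` through `D29`. `D0` counts as
#'   pre-treatment presence.
#' @export
post_start_days <- function() {
  c("D5", "D9", "D14", "D20", "D29")
}

#' @rdname day_levels
#' @export
pre_treatment_days <- function() {
  c("DS", "D-10", "D0")
}

compartment_levels <- function() c("snow", "soil", "flow_through", "lab_control")
experiment_levels <- function() c("melt_rate", "soil_ph")
arm_levels <- function() c("treatment", "control")

condition_levels <- function(experiment) {
  switch(experiment,
    melt_rate = c("average", "fast"),
    soil_ph = c("acidic", "acidoneutral", "alkaline"),
    stop("unknown experiment label: ", experiment, call. = FALSE)
  )
}

#' Validate a sample metadata table
#'
#' Checks the sample metadata against the experimental-design schema: required
#' columns, enum-valued fields (compartment, experiment, arm, day), unique
#' sample identifiers, and condition labels consistent with the experiment
#' each sample belongs to. Lab-control samples (kit and sequencer blanks) are
#' exempt from condition/replicate/day requirements.
#'
#' @param metadata A data frame with columns `sample_id`, `compartment`,
#'   `experiment`, `arm`, `condition`, `replicate`, `day`, and optionally
#'   `denom` (grams of soil or millilitres filtered, for qPCR normalisation).
#' @return The metadata as a tibble with `day` converted to an ordered factor
#'   over [day_levels()], invisibly validated.
#' @export
validate_metadata <- function(metadata) {
  required <- c("sample_id", "compartment", "experiment", "arm",
                "condition", "replicate", "day")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  metadata <- tibble::as_tibble(metadata)
  if (anyDuplicated(metadata$sample_id)) {
    dups <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
    stop("duplicate sample_id(s): ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  bad_comp <- setdiff(unique(metadata$compartment), compartment_levels())
  if (length(bad_comp) > 0) {
    stop("unknown compartment label(s): ", paste(bad_comp, collapse = ", "),
         "; allowed: ", paste(compartment_levels(), collapse = ", "),
         call. = FALSE)
  }
  is_lab <- metadata$compartment == "lab_control"
  expt <- metadata$experiment[!is_lab]
  bad_expt <- setdiff(unique(expt), experiment_levels())
  if (length(bad_expt) > 0) {
    stop("unknown experiment label(s): ", paste(bad_expt, collapse = ", "),
         call. = FALSE)
  }
  bad_arm <- setdiff(unique(metadata$arm[!is_lab]), arm_levels())
  if (length(bad_arm) > 0) {
    stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "),
         call. = FALSE)
  }
  days <- as.character(metadata$day[!is_lab])
  bad_day <- setdiff(unique(days), day_levels())
  if (length(bad_day) > 0) {
    stop("unknown day label(s): ", paste(bad_day, collapse = ", "),
         "; allowed: ", paste(day_levels(), collapse = ", "), call. = FALSE)
  }
  for (ex in intersect(unique(expt), experiment_levels())) {
    rows <- !is_lab & metadata$experiment == ex & metadata$compartment != "snow"
    bad_cond <- setdiff(unique(metadata$condition[rows]), condition_levels(ex))
    if (length(bad_cond) > 0) {
      stop("condition(s) not valid for experiment '", ex, "': ",
           paste(bad_cond, collapse = ", "), call. = FALSE)
    }
  }
  rep_ok <- is_lab | (is.finite(metadata$replicate) & metadata$replicate >= 1)
  if (!all(rep_ok, na.rm = FALSE)) {
    stop("replicate must be a positive integer for non-control samples",
         call. = FALSE)
  }
  if ("denom" %in% names(metadata)) {
    bad <- !is.na(metadata$denom) & metadata$denom <= 0
    if (any(bad)) {
      stop("denom must be positive where present; offending sample(s): ",
           paste(metadata$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  metadata$day <- factor(as.character(metadata$day), levels = day_levels(),
                         ordered = TRUE)
  metadata
}

#' Read and write sample metadata
#'
#' Metadata is stored as a tab-delimited table, one row per sequenced sample,
#' with the columns described in [validate_metadata()].
#'
#' @param path Path to a tab-delimited metadata file.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata A metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  out <- metadata
  out$day <- as.character(out$day)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate an ASV count table
#'
#' The canonical in-memory form of a count table is a tibble whose first
#' column, `asv_id`, holds ASV identifiers and whose remaining columns are
#' samples holding non-negative integer read counts.
#'
#' @param counts A data frame with an `asv_id` column and one numeric column
#'   per sample.
#' @return The counts as a tibble, validated.
#' @export
validate_counts <- function(counts) {
  if (!"asv_id" %in% names(counts)) {
    stop("count table must have an 'asv_id' column", call. = FALSE)
  }
  counts <- tibble::as_tibble(counts)
  if (anyDuplicated(counts$asv_id)) {
    dups <- unique(counts$asv_id[duplicated(counts$asv_id)])
    stop("duplicate asv_id(s): ", paste(dups, collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(counts), "asv_id")
  if (anyDuplicated(sample_cols)) {
    stop("duplicate sample identifiers in count table", call. = FALSE)
  }
  for (sc in sample_cols) {
    v <- counts[[sc]]
    if (!is.numeric(v)) {
      stop("sample column '", sc, "' is not numeric", call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop("invalid count at asv '", counts$asv_id[bad[1]], "', sample '",
           sc, "': ", v[bad[1]],
           " (counts must be finite non-negative integers)", call. = FALSE)
    }
  }
  counts
}

#' Read an ASV count table
#'
#' Reads a tab-delimited ASV-by-sample matrix (or a JSON BIOM file) into the
#' canonical tibble form. Orientation is auto-detected from the header: a
#' leading `asv_id` column means ASVs on rows; a leading `sample_id` column
#' means samples on rows, in which case the table is transposed with a
#' warning.
#'
#' @param path Path to the file.
#' @param format `"tsv_matrix"` (default) or `"biom"` (JSON BIOM, requires
#'   the biomformat package).
#' @return A validated count tibble (see [validate_counts()]).
#' @export
read_asv_counts <- function(path, format = c("tsv_matrix", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package",
           call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    counts <- tibble::as_tibble(m, rownames = "asv_id")
    return(validate_counts(counts))
  }
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  lead <- names(counts)[1]
  if (identical(lead, "sample_id")) {
    warning("count table has samples on rows; transposing to ASVs-by-samples",
            call. = FALSE)
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- counts$sample_id
    counts <- tibble::as_tibble(t(m), rownames = "asv_id")
  } else if (!identical(lead, "asv_id")) {
    stop("count table must start with an 'asv_id' (or 'sample_id') column; ",
         "found '", lead, "'", call. = FALSE)
  }
  validate_counts(counts)
}

#' @rdname read_asv_counts
#' @param counts A count tibble.
#' @export
write_asv_counts <- function(counts, path) {
  readr::write_tsv(validate_counts(counts), path, progress = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Taxonomy is tab-delimited: an `asv_id` column plus one column per rank
#' (typically Kingdom through Genus). Carried as annotation only.
#'
#' @param path Path to the file.
#' @return A tibble with `asv_id` and rank columns.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"asv_id" %in% names(tax)) {
    stop("taxonomy table must have an 'asv_id' column", call. = FALSE)
  }
  tibble::as_tibble(tax)
}

#' Convert a snowmelt rate to a daily input volume
#'
#' Converts a snowmelt rate expressed in millimetres of water equivalent per
#' day (mm we/day) into the volume of meltwater (ml/day) delivered to a
#' cylindrical microcosm column of the given inner diameter. The Arctic
#' average melt rate of 9 mm we/day corresponds to 6.4 ml/day for a 50 ml
#' centrifugal tube; the fast-melt scenario of 35 mm we/day corresponds to
#' 24.7 ml/day.
#'
#' @param rate_mm_we_per_day Snowmelt rate, mm water equivalent per day
#'   (non-negative).
#' @param inner_diameter_mm Column inner diameter in mm. Defaults to 30 mm,
#'   the nominal inner diameter of a 50 ml centrifugal tube.
#' @param digits Decimal places for rounding (half-up); `NULL` returns the
#'   exact value.
#' @return Input volume in ml/day.
#' @export
#' @examples
#' melt_rate_to_volume(9)   # 6.4
#' melt_rate_to_volume(35)  # 24.7
melt_rate_to_volume <- function(rate_mm_we_per_day, inner_diameter_mm = 30,
                                digits = 1) {
  if (any(rate_mm_we_per_day < 0)) {
    stop("melt rate must be non-negative", call. = FALSE)
  }
  if (any(inner_diameter_mm <= 0)) {
    stop("inner diameter must be positive", call. = FALSE)
  }
  # mm/day over a circle of area pi r^2 mm^2 gives mm^3/day; 1 ml = 1000 mm^3
  vol <- rate_mm_we_per_day * pi * (inner_diameter_mm / 2)^2 / 1000
  if (is.null(digits)) {
    return(vol)
  }
  round_half_up(vol, digits)
}

# round half away from zero, matching how printed volumes were rounded
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Microcosm design arithmetic
#'
#' Each experiment set runs its arms (treatment and control for each
#' condition) in parallel triplicates; with 4 arms and 3 replicates this gives
#' the standard 12 microcosms per experiment.
#'
#' @param n_arms Number of arms (condition x treatment/control combinations).
#' @param n_replicates Replicates per arm.
#' @return Number of microcosms.
#' @export
#' @examples
#' microcosms_per_experiment(4, 3)  # 12
microcosms_per_experiment <- function(n_arms = 4, n_replicates = 3) {
  if (n_replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (n_arms < 1) stop("arms must be >= 1", call. = FALSE)
  n_arms * n_replicates
}
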