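#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PERMANOVA result
#'
#' @param x An `mc_permanova` object.
#' @param ... Unused.
#' @return The per-term table: `term`, `df`, `sum_sq`, `r_squared`,
#'   `statistic` (pseudo-F), `p_value`.
#' @method tidy mc_permanova
#' @export
tidy.mc_permanova <- function(x, ...) {
  x$table
}

#' @rdname tidy.mc_permanova
#' @method glance mc_permanova
#' @export
glance.mc_permanova <- function(x, ...) {
  terms <- x$table[!x$table$term %in% c("Residual", "Total"), ]
  tibble::tibble(
    n = x$n,
    n_terms = nrow(terms),
    r_squared_model = sum(terms$r_squared),
    n_permutations = x$n_permutations,
    exhaustive = x$exhaustive
  )
}

#' Tidy a dispersion-homogeneity result
#'
#' @param x An `mc_dispersion` object.
#' @param ... Unused.
#' @return `tidy()`: per-sample distances to the group centroid;
#'   `glance()`: one row with the F statistic and permutation p-value.
#' @method tidy mc_dispersion
#' @export
tidy.mc_dispersion <- function(x, ...) {
  x$distances
}

#' @rdname tidy.mc_dispersion
#' @method glance mc_dispersion
#' @export
glance.mc_dispersion <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    degenerate = x$degenerate
  )
}

#' Tidy a principal-coordinate ordination
#'
#' @param x An `mc_pcoa` object.
#' @param ... Unused.
#' @return `tidy()`: the sample coordinates; `glance()`: eigenvalue
#'   accounting (number of positive/negative eigenvalues, variance explained
#'   by the first two axes).
#' @method tidy mc_pcoa
#' @export
tidy.mc_pcoa <- function(x, ...) {
  x$coordinates
}

#' @rdname tidy.mc_pcoa
#' @method glance mc_pcoa
#' @export
glance.mc_pcoa <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$coordinates),
    n_positive_eig = sum(x$eigenvalues > 0),
    n_negative_eig = sum(x$eigenvalues < 0),
    prop_axis1 = if (length(x$relative_eig) >= 1) x$relative_eig[1]
                 else NA_real_,
    prop_axis2 = if (length(x$relative_eig) >= 2) x$relative_eig[2]
                 else NA_real_
  )
}

#' Tidy colonisation calls
#'
#' @param x An `mc_colonisation` call table.
#' @param ... Unused.
#' @return `tidy()`: the calls as a plain tibble; `glance()`: the
#'   dataset-wide overview from [colonisation_overview()].
#' @method tidy mc_colonisation
#' @export
tidy.mc_colonisation <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mc_colonisation")
  out
}

#' @rdname tidy.mc_colonisation
#' @method glance mc_colonisation
#' @export
glance.mc_colonisation <- function(x, ...) {
  colonisation_overview(x)
}

#' Ordination plot
#'
#' Scatter plot of the first two principal-coordinate axes, with axis labels
#' carrying the proportion of positive-eigenvalue variation explained.
#'
#' @param object An `mc_pcoa` object.
#' @param colour Optional vector (length = samples) mapped to point colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_pcoa
#' @export
autoplot.mc_pcoa <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) {
    stop("ordination has fewer than two positive axes to plot",
         call. = FALSE)
  }
  pct <- round(100 * object$relative_eig[1:2], 1)
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
  p +
    ggplot2::labs(x = paste0("Axis 1 (", pct[1], "%)"),
                  y = paste0("Axis 2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mc_pcoa
#' @method autoplot mc_dispersion
#' @export
autoplot.mc_dispersion <- function(object, ...) {
  ggplot2::ggplot(object$distances,
                  ggplot2::aes(x = .data$group,
                               y = .data$distance_to_centroid)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Distance to group centroid") +
    ggplot2::theme_minimal()
}

#' Plot colonisation status counts per unit
#'
#' @param object An `mc_colonisation` call table.
#' @param ... Unused.
#' @return A ggplot bar chart of invader/colonist/successful counts.
#' @method autoplot mc_colonisation
#' @export
autoplot.mc_colonisation <- function(object, ...) {
  counts <- summarize_colonisation(object) %>%
    tidyr::pivot_longer(c("invaders", "colonists", "successful"),
                        names_to = "category", values_to = "n") %>%
    dplyr::mutate(category = factor(.data$category,
                                    c("invaders", "colonists", "successful")))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$condition, y = .data$n,
                                       fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~experiment, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "ASVs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Invader relative-abundance heatmap
#'
#' Renders the long table from [heatmap_table()] as day-by-ASV tiles,
#' faceted by unit and replicate, successful colonists marked in the row
#' labels.
#'
#' @param ht Output of [heatmap_table()].
#' @return A ggplot object.
#' @export
plot_invader_heatmap <- function(ht) {
  if (nrow(ht) == 0) stop("no invaders to plot", call. = FALSE)
  ht <- ht %>%
    dplyr::mutate(
      day = factor(.data$day, levels = day_levels()),
      label = ifelse(.data$status == "successful_colonist",
                     paste0(.data$asv_id, " *"), .data$asv_id)
    )
  ggplot2::ggplot(ht, ggplot2::aes(x = .data$day, y = .data$label,
                                   fill = log10(.data$relative_abundance +
                                                  1e-6))) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(condition ~ replicate) +
    ggplot2::scale_fill_viridis_c(name = "log10 rel. abund.") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Rarefaction curve plot
#'
#' @param curves A tibble binding one or more [rarefaction_curve()] outputs,
#'   optionally with a `sample_id` column.
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curves) {
  aes <- if ("sample_id" %in% names(curves)) {
    ggplot2::aes(x = .data$depth, y = .data$expected_richness,
                 group = .data$sample_id, colour = .data$sample_id)
  } else {
    ggplot2::aes(x = .data$depth, y = .data$expected_richness)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Reads subsampled", y = "Expected richness") +
    ggplot2::theme_minimal()
}
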