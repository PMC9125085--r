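#' Alpha diversity: richness and Shannon index
#'
#' `richness()` counts taxa detected (count >= 1); `shannon()` computes the
#' Shannon entropy H = -sum p_i log p_i in nats over detected taxa, the
#' conventional default of the ecology package family. H is bounded by
#' log(richness), with equality only for a uniform community.
#'
#' @param sample_counts Non-negative numeric vector of per-taxon counts (or
#'   relative abundances) for one sample; must have a positive total.
#' @return `richness()` an integer; `shannon()` a double (nats).
#' @export
#' @examples
#' shannon(c(1, 2, 3))  # ~1.0114
richness <- function(sample_counts) {
  check_alpha_input(sample_counts)
  sum(sample_counts > 0)
}

#' @rdname richness
#' @export
shannon <- function(sample_counts) {
  check_alpha_input(sample_counts)
  p <- sample_counts[sample_counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

check_alpha_input <- function(x) {
  if (length(x) == 0 || all(x == 0)) {
    stop("sample has no detected taxa", call. = FALSE)
  }
  if (any(x < 0) || any(!is.finite(x))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  invisible(x)
}

#' Per-sample alpha diversity table
#'
#' @param counts A count tibble (see [validate_counts()]).
#' @return A tibble with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  counts <- validate_counts(counts)
  sample_cols <- setdiff(names(counts), "asv_id")
  tibble::tibble(
    sample_id = sample_cols,
    richness = vapply(sample_cols, function(s) richness(counts[[s]]),
                      numeric(1)),
    shannon = vapply(sample_cols, function(s) shannon(counts[[s]]),
                     numeric(1))
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes pairwise Bray-Curtis dissimilarity between samples,
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i): 0 for identical samples, 1 for
#' samples with disjoint taxa. Bray-Curtis is a semimetric — the triangle
#' inequality is not guaranteed.
#'
#' @param x A count or relative-abundance tibble (first column `asv_id`,
#'   samples in columns), or a numeric matrix with samples in columns.
#' @return A [stats::dist] object over the samples.
#' @export
bray_curtis <- function(x) {
  m <- abundance_matrix(x)
  n <- ncol(m)
  if (n < 2) stop("at least two samples are required", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- sum(m[, i] + m[, j])
      if (tot == 0) {
        stop("samples '", colnames(m)[i], "' and '", colnames(m)[j],
             "' are both empty; Bray-Curtis undefined", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / tot
    }
  }
  stats::as.dist(d)
}

abundance_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) {
      colnames(x) <- paste0("S", seq_len(ncol(x)))
    }
    return(x)
  }
  x <- validate_relabund_or_counts(x)
  m <- as.matrix(x[, setdiff(names(x), "asv_id"), drop = FALSE])
  rownames(m) <- x$asv_id
  m
}

# like validate_counts but admits non-integer (relative-abundance) values
validate_relabund_or_counts <- function(x) {
  if (!"asv_id" %in% names(x)) {
    stop("table must have an 'asv_id' column", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  vals <- as.matrix(x[, setdiff(names(x), "asv_id"), drop = FALSE])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("abundances must be finite and non-negative", call. = FALSE)
  }
  x
}

#' Principal coordinate analysis (classical MDS)
#'
#' Embeds a distance matrix by Gower double-centering of -d^2/2 and
#' eigendecomposition. Axes are ordered by decreasing eigenvalue; negative
#' eigenvalues (possible for semimetric input such as Bray-Curtis) are
#' reported but their axes are excluded from the returned coordinates. No
#' Cailliez/Lingoes correction is applied.
#'
#' @param d A [stats::dist] object or symmetric distance matrix.
#' @return An object of class `mc_pcoa`: a list with `coordinates` (tibble:
#'   `sample_id` plus `Axis.1`, `Axis.2`, ...), `eigenvalues` (all of them,
#'   decreasing), and `relative_eig` (positive eigenvalues over their sum).
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8)) {
    stop("d must be a symmetric distance matrix", call. = FALSE)
  }
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(m)))
  G <- gower_center(m)
  eig <- eigen(G, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values[1], 0) * 1e-9 & values > 0)
  coords <- matrix(numeric(0), nrow = nrow(m), ncol = 0)
  if (length(pos) > 0) {
    coords <- eig$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(values[pos]), nrow = length(pos))
    colnames(coords) <- paste0("Axis.", seq_along(pos))
  }
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(sample_id = ids),
        tibble::as_tibble(coords, .name_repair = "minimal")
      ),
      eigenvalues = values,
      relative_eig = if (length(pos) > 0) values[pos] / sum(values[pos])
                     else numeric(0)
    ),
    class = "mc_pcoa"
  )
}

# Gower-centered inner-product matrix: G = -(1/2) J d^2 J with J = I - 11'/n
gower_center <- function(m) {
  A <- -0.5 * m^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' @export
print.mc_pcoa <- function(x, ...) {
  npos <- sum(x$eigenvalues > 0)
  cat("Principal coordinate analysis:", nrow(x$coordinates), "samples,",
      npos, "positive eigenvalue(s)\n")
  if (length(x$relative_eig) > 0) {
    cat("First axes explain",
        paste0(round(100 * utils::head(x$relative_eig, 2), 1), "%",
               collapse = ", "),
        "of positive-eigenvalue variation\n")
  }
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix among the terms
#' of a model formula, with significance assessed by permutation of sample
#' labels. Sums of squares are computed from the Gower-centered matrix with
#' sequential (order-dependent, Type-I) partitioning, so term order is the
#' order in the formula. The p-value uses the add-one estimator
#' p = (1 + #\{permuted F >= observed F\}) / (1 + n_permutations), so p can
#' never be exactly zero; with `n_permutations = "all"` every permutation of
#' the samples is enumerated and p is the exact fraction with F >= observed
#' (identity included).
#'
#' @param d A [stats::dist] or symmetric distance matrix over samples.
#' @param data Data frame of sample-level factors, rows aligned with `d`.
#' @param formula Right-hand-side formula over columns of `data`,
#'   e.g. `~ arm + day`.
#' @param n_permutations Number of random permutations (default 999), or
#'   `"all"` for exhaustive enumeration (requires n <= 8).
#' @param seed Integer seed making the permutations reproducible.
#' @return An object of class `mc_permanova` with a `table` of per-term
#'   df, sums of squares, R-squared, pseudo-F and p-values.
#' @export
permanova <- function(d, data, formula, n_permutations = 999, seed = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  data <- as.data.frame(data)
  if (nrow(data) != n) {
    stop("data must have one row per sample in d", call. = FALSE)
  }
  G <- gower_center(m)
  ss_total <- sum(diag(G))
  terms_obj <- stats::terms(formula)
  term_labels <- attr(terms_obj, "term.labels")
  if (length(term_labels) == 0) stop("formula has no terms", call. = FALSE)

  # cumulative hat matrices, one per sequential model
  hats <- vector("list", length(term_labels))
  ranks <- integer(length(term_labels))
  for (k in seq_along(term_labels)) {
    f_k <- stats::reformulate(term_labels[seq_len(k)])
    X <- stats::model.matrix(f_k, data)
    qr_x <- qr(X)
    ranks[k] <- qr_x$rank
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    hats[[k]] <- Q %*% t(Q)
  }
  prev_rank <- c(1L, ranks[-length(ranks)])
  df_terms <- ranks - prev_rank
  if (any(df_terms == 0)) {
    stop("term '", term_labels[which(df_terms == 0)[1]],
         "' is confounded with preceding terms", call. = FALSE)
  }
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) {
    stop("no residual degrees of freedom: n must exceed model rank",
         call. = FALSE)
  }

  stat_fun <- function(Gp) {
    tr_cum <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    # the intercept's contribution tr((11'/n) G) is 0 for Gower-centered G
    # (rows sum to zero), so successive differences are the term SS
    ss_terms <- diff(c(0, tr_cum))
    ss_res <- sum(diag(Gp)) - tr_cum[length(tr_cum)]
    f_terms <- (ss_terms / df_terms) / (ss_res / df_res)
    list(ss = ss_terms, ss_res = ss_res, f = f_terms)
  }
  obs <- stat_fun(G)

  exhaustive <- identical(n_permutations, "all")
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration is limited to n <= 8",
                    call. = FALSE)
    perms <- all_permutations(n)
    f_perm <- t(vapply(perms, function(p) stat_fun(G[p, p])$f,
                       numeric(length(term_labels))))
    if (length(term_labels) == 1) f_perm <- matrix(f_perm, ncol = 1)
    p_values <- colMeans(sweep(f_perm, 2, obs$f - 1e-12, ">="))
    n_perm_used <- length(perms)
  } else {
    n_permutations <- as.integer(n_permutations)
    f_perm <- withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
      t(vapply(seq_len(n_permutations), function(i) {
        p <- sample.int(n)
        stat_fun(G[p, p])$f
      }, numeric(length(term_labels))))
    })
    if (length(term_labels) == 1) f_perm <- matrix(f_perm, ncol = 1)
    exceed <- colSums(sweep(f_perm, 2, obs$f - 1e-12, ">="))
    p_values <- (1 + exceed) / (1 + n_permutations)
    n_perm_used <- n_permutations
  }

  tab <- tibble::tibble(
    term = c(term_labels, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    sum_sq = c(obs$ss, obs$ss_res, ss_total),
    r_squared = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    statistic = c(obs$f, NA_real_, NA_real_),
    p_value = c(p_values, NA_real_, NA_real_)
  )
  structure(
    list(table = tab, n_permutations = n_perm_used,
         exhaustive = exhaustive, n = n, formula = formula, seed = seed),
    class = "mc_permanova"
  )
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

#' @export
print.mc_permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", x$n_permutations,
      if (x$exhaustive) "exhaustive permutations)\n" else "permutations)\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Multivariate dispersion homogeneity test
#'
#' Tests whether groups have equal multivariate spread around their
#' centroids (the betadisper idea): samples are embedded by principal
#' coordinate analysis, each sample's distance to its group centroid is
#' computed — with negative-eigenvalue axes contributing negatively to the
#' squared distance — and the distances are compared across groups by a
#' one-way ANOVA F, with significance by permutation of group labels.
#'
#' @inheritParams permanova
#' @param groups Factor (or coercible) of group memberships, each group of
#'   size >= 2.
#' @return An object of class `mc_dispersion`: group centroids are by
#'   coordinate mean; `distances` is a tibble of per-sample distances;
#'   `statistic`, `p_value`, `n_permutations` describe the test. When all
#'   distances are zero the statistic is degenerate and reported as `NA`
#'   with `degenerate = TRUE`.
#' @export
dispersion_test <- function(d, groups, n_permutations = 999, seed = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- factor(groups)
  if (length(groups) != n) {
    stop("groups must have one entry per sample", call. = FALSE)
  }
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least two members", call. = FALSE)
  }
  G <- gower_center(m)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  pos <- eig$values > tol
  neg <- eig$values < -tol
  cr <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), nrow = sum(pos))
  ci <- eig$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eig$values[neg]), nrow = sum(neg))
  z2 <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cen_r <- colMeans(cr[idx, , drop = FALSE])
    cen_i <- colMeans(ci[idx, , drop = FALSE])
    dr <- sweep(cr[idx, , drop = FALSE], 2, cen_r)
    di <- sweep(ci[idx, , drop = FALSE], 2, cen_i)
    z2[idx] <- rowSums(dr^2) - rowSums(di^2)
  }
  z <- sqrt(pmax(z2, 0))

  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  f_of <- function(grp) one_way_f(z, grp)
  obs <- f_of(groups)
  if (!is.finite(obs)) {
    return(structure(
      list(distances = tibble::tibble(sample_id = ids, group = groups,
                                      distance_to_centroid = z),
           statistic = NA_real_, p_value = NA_real_,
           n_permutations = 0L, degenerate = TRUE),
      class = "mc_dispersion"
    ))
  }
  n_permutations <- as.integer(n_permutations)
  f_perm <- withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
    vapply(seq_len(n_permutations),
           function(i) f_of(groups[sample.int(n)]), numeric(1))
  })
  p <- (1 + sum(f_perm >= obs - 1e-12, na.rm = TRUE)) / (1 + n_permutations)
  structure(
    list(distances = tibble::tibble(sample_id = ids, group = groups,
                                    distance_to_centroid = z),
         statistic = obs, p_value = p,
         n_permutations = n_permutations, degenerate = FALSE),
    class = "mc_dispersion"
  )
}

# one-way ANOVA F on a numeric response. Sums of squares below a relative
# tolerance are treated as exactly zero so that numerically constant
# responses (e.g. equal distances to centroid) give F = 0, and the fully
# degenerate all-zero case propagates NaN.
one_way_f <- function(y, groups) {
  groups <- factor(groups)
  gm <- tapply(y, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.integer(groups)])^2)
  tol <- length(y) * mean(y^2) * 1e-12
  if (ssb <= tol && ssw <= tol) {
    if (mean(y^2) == 0) return(NaN)
    return(0)
  }
  if (ssb <= tol) ssb <- 0
  df1 <- nlevels(groups) - 1
  df2 <- length(y) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

#' @export
print.mc_dispersion <- function(x, ...) {
  if (x$degenerate) {
    cat("Dispersion homogeneity test: degenerate (all distances to",
        "centroid are zero)\n")
  } else {
    cat("Dispersion homogeneity test: F =", format(x$statistic, digits = 4),
        ", p =", format(x$p_value, digits = 4),
        "(", x$n_permutations, "permutations)\n")
  }
  invisible(x)
}

#' Sequential (Type-I) factorial ANOVA
#'
#' Fits a factorial ANOVA with sequential sums of squares — the classical
#' order-dependent decomposition where each term is adjusted only for the
#' terms before it — supporting main effects and interactions
#' (e.g. `response ~ rate * treatment * day`). Thin tidy wrapper over
#' [stats::aov]; aliased terms are rejected rather than silently dropped.
#'
#' @param data Data frame holding the response and factors.
#' @param formula Model formula, response on the left.
#' @return A tibble with columns `term`, `df`, `sum_sq`, `mean_sq`,
#'   `statistic`, `p_value` (Residuals row included).
#' @export
anova_sequential <- function(data, formula) {
  data <- as.data.frame(data)
  terms_obj <- stats::terms(formula, data = data)
  term_labels <- attr(terms_obj, "term.labels")
  # reject aliasing explicitly: every sequential term must add model rank
  rhs_rank <- 1L
  for (k in seq_along(term_labels)) {
    X <- stats::model.matrix(stats::reformulate(term_labels[seq_len(k)]),
                             data)
    r <- qr(X)$rank
    if (r == rhs_rank) {
      stop("term '", term_labels[k],
           "' is aliased with preceding terms", call. = FALSE)
    }
    rhs_rank <- r
  }
  fit <- stats::aov(formula, data = data)
  tab <- summary(fit)[[1]]
  out <- tibble::tibble(
    term = trimws(rownames(tab)),
    df = tab[["Df"]],
    sum_sq = tab[["Sum Sq"]],
    mean_sq = tab[["Mean Sq"]],
    statistic = tab[["F value"]],
    p_value = tab[["Pr(>F)"]]
  )
  response <- stats::model.response(stats::model.frame(formula, data))
  if (stats::var(response) == 0) {
    # constant response: nothing to partition, F = 0 for every term
    fitted_terms <- out$term != "Residuals"
    out$statistic[fitted_terms] <- 0
    out$p_value[fitted_terms] <- 1
  }
  out
}

#' Tukey HSD pairwise comparisons with optional Bonferroni family correction
#'
#' Studentized-range-based pairwise comparisons after a one-way ANOVA, with
#' an optional Bonferroni multiplication across `n_families` test families —
#' the combination used when several response variables are screened at once.
#' When the within-group variance is exactly zero but group means differ, the
#' limiting p-value 0 is reported.
#'
#' @param data Data frame with the response and grouping columns.
#' @param formula One-way formula `response ~ group`.
#' @param n_families Number of test families for Bonferroni correction
#'   (1 = none). Adjusted p-values are capped at 1 and never decrease.
#' @return A tibble with `contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `p_value` (Tukey-adjusted), `p_adjusted` (after Bonferroni).
#' @export
tukey_hsd <- function(data, formula, n_families = 1) {
  data <- as.data.frame(data)
  if (n_families < 1) stop("n_families must be >= 1", call. = FALSE)
  fit <- stats::aov(formula, data = data)
  tab <- summary(fit)[[1]]
  mse <- tab[["Mean Sq"]][nrow(tab)]
  hsd <- suppressWarnings(stats::TukeyHSD(fit))[[1]]
  p <- hsd[, "p adj"]
  if (isTRUE(mse == 0)) {
    # zero within-group variance: p -> 0 where means differ, 1 where equal
    p <- ifelse(abs(hsd[, "diff"]) > 0, 0, 1)
  }
  tibble::tibble(
    contrast = rownames(hsd),
    estimate = hsd[, "diff"],
    conf_low = hsd[, "lwr"],
    conf_high = hsd[, "upr"],
    p_value = unname(p),
    p_adjusted = pmin(unname(p) * n_families, 1)
  )
}

#' qPCR gene-copy normalisation
#'
#' Converts 16S rRNA gene copies per qPCR reaction into copies per gram of
#' soil or per millilitre of snow/flow-through filtered:
#' `copies_per_reaction * (eluate_volume_ul / template_volume_ul) / denom`.
#' The eluate/template ratio scales the reaction back to the whole DNA
#' extract; `denom` is the mass (g) or volume (ml) the extract represents.
#'
#' @param qpcr A data frame with columns `copies_per_reaction`,
#'   `eluate_volume_ul`, `template_volume_ul` and `denom`.
#' @return The input as a tibble with a `copies_per_unit` column added.
#' @export
#' @examples
#' qpcr_copies_per_unit(data.frame(
#'   copies_per_reaction = 100, eluate_volume_ul = 100,
#'   template_volume_ul = 2, denom = 0.25
#' ))$copies_per_unit  # 20000
qpcr_copies_per_unit <- function(qpcr) {
  needed <- c("copies_per_reaction", "eluate_volume_ul",
              "template_volume_ul", "denom")
  missing <- setdiff(needed, names(qpcr))
  if (length(missing) > 0) {
    stop("qpcr table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  qpcr <- tibble::as_tibble(qpcr)
  if (any(is.na(qpcr$denom) | qpcr$denom <= 0)) {
    stop("denom must be present and positive for every sample",
         call. = FALSE)
  }
  if (any(qpcr$template_volume_ul <= 0)) {
    stop("template volume must be positive", call. = FALSE)
  }
  if (any(qpcr$copies_per_reaction < 0)) {
    stop("copies_per_reaction must be non-negative", call. = FALSE)
  }
  dplyr::mutate(
    qpcr,
    copies_per_unit = .data$copies_per_reaction *
      (.data$eluate_volume_ul / .data$template_volume_ul) / .data$denom
  )
}
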