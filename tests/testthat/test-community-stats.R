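test_that("richness and Shannon behave as entropy of detected taxa", {
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(rep(3, 4)), log(4))
  expect_equal(shannon(c(1, 2, 3)),
               -sum((1:3) / 6 * log((1:3) / 6)))  # ~1.0114
  expect_equal(richness(c(1, 0, 2, 0)), 2)
  expect_error(shannon(c(0, 0)), "no detected taxa")

  set.seed(7)
  for (i in 1:20) {
    x <- rpois(10, 3)
    if (all(x == 0)) x[1] <- 1
    expect_lte(shannon(x), log(richness(x)) + 1e-12)
  }
})

test_that("Bray-Curtis matches its definition and the vegan oracle", {
  m <- cbind(a = c(1, 2), b = c(2, 1), c = c(1, 2), d = c(0, 5))
  rownames(m) <- c("t1", "t2")
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 2 / 6)
  expect_equal(d["a", "c"], 0)
  disjoint <- cbind(x = c(3, 0), y = c(0, 4))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)

  set.seed(21)
  rnd <- matrix(rpois(60, 4), nrow = 10,
                dimnames = list(NULL, paste0("s", 1:6)))
  ours <- as.matrix(bray_curtis(rnd))
  veg <- as.matrix(vegan::vegdist(t(rnd), method = "bray"))
  expect_equal(ours, veg, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(ours >= 0 & ours <= 1))
})

test_that("PCoA recovers 1-D configurations and reconstructs distances", {
  pts <- c(0, 1, 4, 5)
  ord <- pcoa_ordination(dist(pts))
  expect_equal(ord$eigenvalues[1], sum((pts - mean(pts))^2))  # 17
  expect_equal(sum(abs(ord$eigenvalues[-1])), 0, tolerance = 1e-8)
  ax1 <- ord$coordinates$Axis.1
  centered <- pts - mean(pts)
  expect_true(max(abs(ax1 - centered)) < 1e-8 ||
                max(abs(ax1 + centered)) < 1e-8)

  # identical points: all eigenvalues zero
  flat <- pcoa_ordination(matrix(0, 3, 3))
  expect_equal(flat$eigenvalues, rep(0, 3))

  # Euclidean input: distances reconstructed from all positive axes
  set.seed(13)
  X <- matrix(rnorm(5 * 3), 5, 3)
  ord2 <- pcoa_ordination(dist(X))
  coords <- as.matrix(ord2$coordinates[-1])
  expect_equal(as.matrix(dist(coords)), as.matrix(dist(X)),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("PERMANOVA on the 1-D toy gives F = 32 and exhaustive p = 1/3", {
  d <- dist(c(0, 1, 4, 5))
  fac <- data.frame(g = factor(c("a", "a", "b", "b")))
  res <- permanova(d, fac, ~g, n_permutations = "all")
  tab <- tidy(res)
  expect_equal(tab$statistic[1], 32)
  expect_equal(tab$r_squared[1], 16 / 17)
  expect_equal(tab$p_value[1], 1 / 3)
})

test_that("PERMANOVA on Euclidean 1-D data equals classical ANOVA F", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    y <- round(rnorm(n, sd = 2), 2)
    g <- factor(sample(rep(c("a", "b"), length.out = n)))
    if (nlevels(g) < 2 || any(table(g) < 1)) next
    res <- permanova(dist(y), data.frame(g = g), ~g, n_permutations = 19,
                     seed = i)
    f_aov <- summary(stats::aov(y ~ g))[[1]]["g", "F value"]
    expect_equal(tidy(res)$statistic[1], f_aov, tolerance = 1e-10)
  }
})

test_that("PERMANOVA sequential partitioning matches vegan::adonis2", {
  set.seed(77)
  comm <- matrix(rpois(12 * 8, 6), nrow = 8,
                 dimnames = list(NULL, paste0("s", 1:12)))
  md <- data.frame(
    A = factor(rep(c("x", "y"), each = 6)),
    B = factor(rep(c("p", "q", "r"), times = 4))
  )
  d <- bray_curtis(comm)
  ours <- tidy(permanova(d, md, ~ A + B, n_permutations = 99, seed = 1))
  veg <- as.data.frame(vegan::adonis2(d ~ A + B, data = md, by = "terms",
                                      permutations = 99))
  expect_equal(ours$sum_sq, veg$SumOfSqs, tolerance = 1e-8)
  expect_equal(ours$statistic[1:2], veg$F[1:2], tolerance = 1e-8)
  expect_equal(ours$r_squared, veg$R2, tolerance = 1e-8)
})

test_that("PERMANOVA partitions the total sum of squares", {
  set.seed(5)
  comm <- matrix(rpois(80, 5), nrow = 8,
                 dimnames = list(NULL, paste0("s", 1:10)))
  d <- bray_curtis(comm)
  g <- data.frame(g = factor(rep(c("a", "b"), 5)))
  tab <- tidy(permanova(d, g, ~g, n_permutations = 29, seed = 2))
  expect_equal(sum(tab$sum_sq[1:2]), tab$sum_sq[3], tolerance = 1e-8)
})

test_that("permutation procedures are reproducible given a seed", {
  set.seed(17)
  comm <- matrix(rpois(60, 5), nrow = 6,
                 dimnames = list(NULL, paste0("s", 1:10)))
  d <- bray_curtis(comm)
  g <- data.frame(g = factor(rep(c("a", "b"), 5)))
  p1 <- tidy(permanova(d, g, ~g, n_permutations = 99, seed = 42))$p_value[1]
  p2 <- tidy(permanova(d, g, ~g, n_permutations = 99, seed = 42))$p_value[1]
  expect_identical(p1, p2)
  d1 <- dispersion_test(d, g$g, n_permutations = 99, seed = 42)
  d2 <- dispersion_test(d, g$g, n_permutations = 99, seed = 42)
  expect_identical(glance(d1), glance(d2))
  # p can never be exactly zero under the add-one estimator
  expect_gte(p1, 1 / 100)
})

test_that("confounded factors are rejected", {
  d <- dist(c(0, 1, 4, 5))
  md <- data.frame(g = factor(c("a", "a", "b", "b")),
                   h = factor(c("u", "u", "v", "v")))
  expect_error(permanova(d, md, ~ g + h, n_permutations = 9, seed = 1),
               "confounded")
})

test_that("dispersion test matches symmetric toys and scales correctly", {
  d <- dist(c(0, 1, 4, 5))
  grp <- c("a", "a", "b", "b")
  res <- dispersion_test(d, grp, n_permutations = 49, seed = 1)
  expect_equal(tidy(res)$distance_to_centroid, rep(0.5, 4))
  expect_equal(res$statistic, 0)

  # doubling all distances doubles centroid distances, F unchanged
  res2 <- dispersion_test(dist(2 * c(0, 1, 4, 5)), grp,
                          n_permutations = 49, seed = 1)
  expect_equal(tidy(res2)$distance_to_centroid,
               2 * tidy(res)$distance_to_centroid)
  expect_equal(res2$statistic, res$statistic)

  # all samples identical: degenerate no-dispersion case
  res3 <- dispersion_test(matrix(0, 4, 4), grp, n_permutations = 49,
                          seed = 1)
  expect_true(res3$degenerate)
  expect_true(is.na(res3$statistic))
})

test_that("dispersion distances agree with vegan::betadisper", {
  set.seed(23)
  comm <- matrix(rpois(10 * 8, 5), nrow = 10,
                 dimnames = list(NULL, paste0("s", 1:8)))
  d <- bray_curtis(comm)
  grp <- factor(rep(c("a", "b"), each = 4))
  ours <- dispersion_test(d, grp, n_permutations = 99, seed = 3)
  bd <- vegan::betadisper(d, grp, type = "centroid")
  expect_equal(unname(tidy(ours)$distance_to_centroid),
               unname(bd$distances), tolerance = 1e-8)
  f_ref <- stats::anova(bd)["Groups", "F value"]
  expect_equal(ours$statistic, f_ref, tolerance = 1e-8)
})

test_that("sequential ANOVA reproduces hand-computed fixtures", {
  df <- data.frame(y = c(1, 2, 3, 2, 3, 4),
                   g = factor(rep(c("a", "b"), each = 3)))
  tab <- anova_sequential(df, y ~ g)
  expect_equal(tab$df[1:2], c(1, 4))
  expect_equal(tab$statistic[1], 1.5)  # SSB 1.5 on SSW 4/4

  const <- data.frame(y = rep(2, 6), g = factor(rep(c("a", "b"), 3)))
  tab0 <- anova_sequential(const, y ~ g)
  expect_equal(tab0$statistic[1], 0)

  # additive two-way balanced design: interaction SS vanishes
  dd <- expand.grid(a = factor(c("a1", "a2")), b = factor(c("b1", "b2")),
                    rep = 1:2)
  dd$y <- c(a1 = 0, a2 = 2)[dd$a] + c(b1 = 0, b2 = 5)[dd$b]
  tab2 <- anova_sequential(dd, y ~ a * b)
  expect_equal(tab2$sum_sq[tab2$term == "a:b"], 0, tolerance = 1e-12)

  dd$alias <- dd$a
  expect_error(anova_sequential(dd, y ~ a + alias), "aliased")
})

test_that("Tukey HSD reduces to the t-test for two groups", {
  df <- data.frame(y = c(1.2, 2.1, 2.9, 2.4, 3.3, 4.0),
                   g = factor(rep(c("a", "b"), each = 3)))
  hsd <- tukey_hsd(df, y ~ g)
  t_p <- stats::t.test(y ~ g, df, var.equal = TRUE)$p.value
  expect_equal(hsd$p_value, t_p, tolerance = 1e-5)

  same <- data.frame(y = rep(c(1, 2, 3), 3),
                     g = factor(rep(c("a", "b", "c"), each = 3)))
  expect_true(all(tukey_hsd(same, y ~ g)$p_value > 0.999))

  # Bonferroni across families never decreases p, and caps at 1
  hsd3 <- tukey_hsd(df, y ~ g, n_families = 3)
  expect_true(all(hsd3$p_adjusted >= hsd3$p_value))
  expect_true(all(hsd3$p_adjusted <= 1))
})

test_that("qPCR normalisation applies the eluate ratio and denominator", {
  q <- tibble::tibble(copies_per_reaction = c(100, 0, 100),
                      eluate_volume_ul = 100, template_volume_ul = 2,
                      denom = c(0.25, 0.25, 0.5))
  out <- qpcr_copies_per_unit(q)
  expect_equal(out$copies_per_unit, c(20000, 0, 10000))
  expect_error(qpcr_copies_per_unit(dplyr::mutate(q, denom = NA)), "denom")
})
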