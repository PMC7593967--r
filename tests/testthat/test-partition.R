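test_that("one-way ANOVA matches textbook identities", {
  # groups (1,2,3) vs (4,5,6): hand SS -> F = 13.5
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 13.5, tolerance = 1e-12)
  # F equals the squared equal-variance t statistic
  set.seed(1)
  y <- rnorm(12)
  g <- rep(c("a", "b"), each = 6)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(one_way_anova(y, g)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  # location invariance
  expect_equal(one_way_anova(y + 100, g)$statistic,
               one_way_anova(y, g)$statistic, tolerance = 1e-9)
  # degenerate constant response -> F = 0, p = 1
  z <- one_way_anova(rep(2, 8), rep(c("a", "b"), 4))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(one_way_anova(y, rep("a", 12)), "two groups")
})

test_that("sequential factorial ANOVA matches hand-computed sums of squares", {
  # balanced 2x2, cell means planted exactly, no noise
  design <- data.frame(a = rep(c("a1", "a2"), each = 4),
                       b = rep(c("b1", "b2"), 4))
  mu <- c(a1b1 = 10, a1b2 = 12, a2b1 = 20, a2b2 = 26)
  y <- mu[paste0(design$a, design$b)]
  fit <- anova_factorial(y, design, terms = c("a", "b", "a:b"))
  # independent oracle: direct deviation sums on the balanced design
  ss_a <- sum(tapply(y, design$a, function(v) length(v) * (mean(v) - mean(y))^2))
  ss_b <- sum(tapply(y, design$b, function(v) length(v) * (mean(v) - mean(y))^2))
  cell_means <- tapply(y, paste0(design$a, design$b), mean)
  ss_cells <- sum(2 * (cell_means - mean(y))^2)
  expect_equal(fit$table$sum_sq[1], ss_a, tolerance = 1e-10)
  expect_equal(fit$table$sum_sq[2], ss_b, tolerance = 1e-10)
  expect_equal(fit$table$sum_sq[3], ss_cells - ss_a - ss_b, tolerance = 1e-10)
  expect_equal(fit$table$sum_sq[4], 0, tolerance = 1e-10)
  # partition identity
  expect_equal(sum(fit$table$sum_sq), sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(sum(fit$table$df), length(y) - 1)
})

test_that("model reduction honours significance and hierarchy", {
  set.seed(5)
  design <- data.frame(dose = rep(c("high", "low"), each = 16),
                       frequency = rep(rep(c("1", "4"), each = 8), 2))
  # only the dose:frequency interaction carries signal
  y <- ifelse(design$dose == "high", 1, -1) *
    ifelse(design$frequency == "1", 1, -1) + rnorm(32, sd = 0.3)
  full <- anova_factorial(y, design, terms = c("dose", "frequency",
                                               "dose:frequency"))
  red <- reduce_model(full, alpha = 0.05)
  expect_true("dose:frequency" %in% red$retained)
  expect_true(all(c("dose", "frequency") %in% red$retained))

  # all terms significant -> reduced model = full model
  y2 <- as.numeric(factor(design$dose)) * 3 +
    as.numeric(factor(design$frequency)) + rnorm(32, sd = 0.1)
  full2 <- anova_factorial(y2, design, terms = c("dose", "frequency"))
  red2 <- reduce_model(full2)
  expect_equal(red2$retained, c("dose", "frequency"))
  expect_equal(red2$table$sum_sq, full2$table$sum_sq)

  # nothing significant -> intercept-only with 100% residual partition
  y3 <- rnorm(32)
  full3 <- anova_factorial(rep(c(0, 0.001), 16), design,
                           terms = c("dose", "frequency"))
  red3 <- reduce_model(full3, alpha = 1e-6)
  expect_true(red3$no_significant_terms)
  vp <- variance_components_anova(red3)
  expect_equal(vp$percent, 100)
  expect_equal(vp$term, "Residuals")
})

test_that("omega-squared components behave at the limits", {
  design <- data.frame(g = rep(c("a", "b", "c"), each = 10))
  # noise-free single factor: component -> ~100%
  y <- rep(c(0, 5, 9), each = 10)
  fit <- anova_factorial(y, design, terms = "g")
  vp <- variance_components_anova(fit)
  expect_gt(vp$percent[vp$term == "g"], 99)
  expect_equal(sum(vp$percent), 100, tolerance = 1e-9)
  # pure noise: mean component small (null simulation)
  set.seed(11)
  comp <- replicate(200, {
    f <- anova_factorial(rnorm(30), design, terms = "g")
    variance_components_anova(f)$percent[1]
  })
  expect_lt(mean(comp), 2)
})

test_that("PERMANOVA on Euclidean univariate data equals classical ANOVA", {
  set.seed(2)
  for (i in 1:10) {
    y <- rnorm(21)
    g <- factor(rep(letters[1:3], 7))
    d <- as.matrix(dist(y))
    pf <- permanova(d, data.frame(g = g), terms = "g", n_perm = 99, seed = i)
    af <- anova_factorial(y, data.frame(g = g), terms = "g")
    expect_equal(pf$table$pseudo_f[1], af$table$f_value[1], tolerance = 1e-8)
    expect_equal(pf$ss_total, af$ss_total, tolerance = 1e-8)
  }
})

test_that("PERMANOVA agrees with an independent implementation on multifactor data", {
  set.seed(3)
  n <- 24
  design <- data.frame(a = factor(rep(c("x", "y"), each = 12)),
                       b = factor(rep(rep(c("u", "v", "w"), each = 4), 2)))
  comm <- matrix(rpois(n * 10, 20), n)
  rownames(comm) <- paste0("S", 1:n)
  colnames(comm) <- paste0("O", 1:10)
  d <- bray_curtis(comm)
  mine <- permanova(d, design, terms = c("a", "b", "a:b"), n_perm = 199, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ a * b, data = design, permutations = 199,
                        by = "terms")
  expect_equal(mine$table$sum_sq[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(mine$table$pseudo_f[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(mine$table$sum_sq[4], ref$SumOfSqs[4], tolerance = 1e-8)
})

test_that("PERMANOVA p-values honour the +1 permutation convention", {
  # two point clouds far apart: p attains its minimum 1/(n_perm + 1)
  y <- c(rnorm(8), rnorm(8) + 100)
  d <- as.matrix(dist(y))
  g <- rep(c("a", "b"), each = 8)
  fit <- permanova(d, data.frame(g = g), terms = "g", n_perm = 199, seed = 4)
  expect_equal(fit$table$p_value[1], 1 / 200, tolerance = 1e-12)
})

test_that("duplicated group structure carries no between-group signal", {
  set.seed(6)
  y <- matrix(rnorm(16), 8)
  coords <- rbind(y, y)  # identical clouds in both groups
  d <- as.matrix(dist(coords))
  g <- rep(c("a", "b"), each = 8)
  fit <- permanova(d, data.frame(g = g), terms = "g", n_perm = 99, seed = 1)
  expect_lt(fit$table$sum_sq[1] / fit$ss_total, 0.02)
})

test_that("PERMANOVA percent components sum to 100 and match null expectation", {
  set.seed(8)
  # strong single factor: component near 100%
  y <- c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1))
  d <- as.matrix(dist(y))
  fit <- permanova(d, data.frame(g = rep(c("a", "b"), each = 10)),
                   terms = "g", n_perm = 99, seed = 1)
  vp <- variance_components_permanova(fit)
  expect_gt(vp$percent[vp$term == "g"], 99)
  expect_equal(sum(vp$percent), 100, tolerance = 1e-9)
  # null data: expected share ~ df/(n-1)
  shares <- replicate(60, {
    yy <- matrix(rnorm(24), 12)
    dd <- as.matrix(dist(yy))
    f <- permanova(dd, data.frame(g = factor(rep(1:3, 4))), terms = "g",
                   n_perm = 99, seed = NULL)
    f$table$sum_sq[1] / f$ss_total
  })
  expect_lt(abs(mean(shares) - 2 / 11), 0.03)
})

test_that("pairwise PERMANOVA adjusts p-values over all group pairs", {
  set.seed(9)
  # two separated clouds plus one coincident with the first
  base <- matrix(rnorm(12), 6)
  far <- matrix(rnorm(12, 30), 6)
  coords <- rbind(base, far, base + matrix(rnorm(12, 0, 0.01), 6))
  d <- as.matrix(dist(coords))
  g <- rep(c("a", "b", "c"), each = 6)
  pw <- pairwise_permanova(d, g, n_perm = 199, seed = 2)
  expect_equal(nrow(pw), choose(3, 2))
  sep <- pw$p_adjusted[(pw$group1 == "a" & pw$group2 == "b") |
                         (pw$group1 == "b" & pw$group2 == "c")]
  expect_true(all(sep < 0.05))
  expect_gt(pw$p_adjusted[pw$group1 == "a" & pw$group2 == "c"], 0.1)

  # three identical groups: all adjusted p near 1
  same <- rbind(base, base, base)
  dsame <- as.matrix(dist(same))
  pw2 <- pairwise_permanova(dsame, g, n_perm = 99, seed = 3)
  expect_true(all(pw2$p_adjusted > 0.5))

  # a singleton group is skipped with a warning
  g3 <- c(rep("a", 6), rep("b", 6), rep("c", 5), "d")
  w <- testthat::capture_warnings(
    pw3 <- pairwise_permanova(d, g3, n_perm = 99, seed = 4))
  expect_length(w, 3)  # every pair involving the singleton group
  expect_match(w, "skipped", all = TRUE)
  expect_equal(nrow(pw3), 3)
})

test_that("aliased terms and invalid inputs are rejected", {
  design <- data.frame(a = rep(c("x", "y"), 6), b = rep(c("x", "y"), 6))
  y <- rnorm(12)
  expect_error(anova_factorial(y, design, terms = c("a", "b")), "aliased.*b")
  d <- as.matrix(dist(y))
  expect_error(permanova(d, design, terms = c("a", "b"), n_perm = 99), "aliased")
  dbad <- d; dbad[1, 2] <- dbad[1, 2] + 1
  expect_error(permanova(dbad, design, terms = "a", n_perm = 99), "symmetric")
})
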