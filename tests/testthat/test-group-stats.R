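# ---- per-animal aggregation ------------------------------------------

test_that("per-animal aggregation is the unweighted cell mean", {
  d <- data.frame(cell_id = rep(c("c1", "c2", "c3"), each = 2),
                  animal_id = rep(c("a1", "a1", "a2"), each = 2),
                  genotype = "WT", level = rep(0:1, 3),
                  value = c(10, 20, 30, 40, 7, 8))
  pm <- aggregate_per_animal(d)
  expect_equal(pm$value[pm$unit == "a1"], c(20, 30))
  expect_equal(pm$value[pm$unit == "a2"], c(7, 8))  # single-cell animal
})

test_that("aggregation zero-fills levels a cell does not reach", {
  d <- data.frame(cell_id = c("c1", "c1", "c2"),
                  animal_id = "a1", genotype = "WT",
                  level = c(0, 1, 0), value = c(10, 6, 30))
  pm <- aggregate_per_animal(d)
  expect_equal(pm$value, c(20, 3))   # c2 contributes 0 at level 1
})

test_that("aggregation matches a brute-force group-by mean", {
  set.seed(14)
  d <- expand.grid(cell_id = sprintf("c%02d", 1:30), level = 0:8)
  d$animal_id <- sprintf("a%d", (as.integer(factor(d$cell_id)) - 1) %/% 6)
  d$genotype <- ifelse(d$animal_id < "a3", "WT", "MeCP2+")
  d$value <- rnorm(nrow(d))
  pm <- aggregate_per_animal(d)
  for (i in sample(nrow(pm), 12)) {
    cells <- unique(d$cell_id[d$animal_id == pm$unit[i]])
    vals <- vapply(cells, function(cc)
      d$value[d$cell_id == cc & d$level == pm$level[i]], numeric(1))
    expect_equal(pm$value[i], mean(vals))
  }
})

# ---- repeated-measures ANOVA -----------------------------------------

test_that("mixed RM-ANOVA matches the longhand sums-of-squares oracle", {
  set.seed(5)
  for (rep in 1:3) {
    pm <- expand.grid(unit = sprintf("u%d", 1:8), level = 1:5)
    pm$genotype <- ifelse(as.integer(factor(pm$unit)) <= 4, "g1", "g2")
    pm$value <- rnorm(nrow(pm)) + as.integer(factor(pm$unit)) * 0.3 +
      (pm$genotype == "g2") * pm$level * 0.2
    fit <- rm_anova(pm)
    orc <- oracle_rm_anova(pm)
    tab <- fit$anova_table
    expect_equal(tab$F[tab$effect == "genotype"], orc$F_genotype,
                 tolerance = 1e-10)
    expect_equal(tab$F[tab$effect == "level"], orc$F_level,
                 tolerance = 1e-10)
    expect_equal(tab$F[tab$effect == "genotype:level"],
                 orc$F_interaction, tolerance = 1e-10)
  }
})

test_that("RM-ANOVA df follow from the declared design", {
  # 3 genotypes x 5 animals, 23 within levels -> interaction df (44, 264)
  pm <- expand.grid(unit = sprintf("u%02d", 1:15), level = 1:23)
  pm$genotype <- c("WT", "MeCP2+", "MeCP2-")[
    (as.integer(factor(pm$unit)) - 1) %/% 5 + 1]
  set.seed(8); pm$value <- rnorm(nrow(pm))
  tab <- rm_anova(pm, posthoc = FALSE)$anova_table
  expect_equal(tab$df1[tab$effect == "genotype:level"], 44)
  expect_equal(tab$df2[tab$effect == "genotype:level"], 264)
  expect_equal(tab$df1[tab$effect == "genotype"], 2)
  expect_equal(tab$df2[tab$effect == "genotype"], 12)
})

test_that("identical genotype groups give zero genotype F and capped p", {
  base <- expand.grid(unit = sprintf("u%d", 1:6), level = 1:4)
  base$genotype <- ifelse(as.integer(factor(base$unit)) <= 3, "g1", "g2")
  set.seed(3)
  per_unit <- rnorm(3)[(as.integer(factor(base$unit)) - 1) %% 3 + 1]
  base$value <- per_unit + base$level * 0.5   # g2 duplicates g1 exactly
  fit <- rm_anova(base)
  tab <- fit$anova_table
  expect_equal(tab$F[tab$effect == "genotype"], 0, tolerance = 1e-10)
  expect_true(all(fit$posthoc$p_adj == 1))
})

test_that("a constant genotype shift moves the main effect, not the interaction", {
  set.seed(9)
  pm <- expand.grid(unit = sprintf("u%d", 1:10), level = 1:6)
  pm$genotype <- ifelse(as.integer(factor(pm$unit)) <= 5, "g1", "g2")
  pm$value <- rnorm(nrow(pm))
  f0 <- rm_anova(pm, posthoc = FALSE)$anova_table
  shifted <- pm
  shifted$value <- shifted$value + (shifted$genotype == "g2") * 5
  f1 <- rm_anova(shifted, posthoc = FALSE)$anova_table
  expect_gt(f1$F[f1$effect == "genotype"], f0$F[f0$effect == "genotype"])
  expect_equal(f1$F[f1$effect == "genotype:level"],
               f0$F[f0$effect == "genotype:level"], tolerance = 1e-10)
})

test_that("incomplete profile matrices are refused with guidance", {
  pm <- expand.grid(unit = c("u1", "u2", "u3", "u4"), level = 1:3)
  pm$genotype <- ifelse(pm$unit %in% c("u1", "u2"), "g1", "g2")
  pm$value <- rnorm(nrow(pm))
  expect_error(rm_anova(pm[-1, ]), "truncate")
})

# ---- one-way ANOVA ----------------------------------------------------

test_that("one-way ANOVA matches the textbook decomposition", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  res <- one_way_anova(g)
  k <- 3; n <- 9
  grand <- mean(unlist(g))
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  expect_equal(res$F, (ss_b / (k - 1)) / (ss_w / (n - k)),
               tolerance = 1e-12)
  expect_equal(res$df1, 2); expect_equal(res$df2, 6)
  # five units per group in three groups reports df (2, 12)
  set.seed(1)
  g5 <- list(rnorm(5), rnorm(5), rnorm(5))
  r5 <- one_way_anova(g5)
  expect_equal(c(r5$df1, r5$df2), c(2, 12))
  ident <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$F, 0, tolerance = 1e-12)
  expect_error(one_way_anova(list(c(1, 2), c(3))), "at least two values")
})

# ---- rank tests -------------------------------------------------------

test_that("Mann-Whitney exact branch reproduces the enumeration oracle", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_true(res$exact)
  set.seed(21)
  for (i in 1:12) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    v <- sample(100, m + n)           # distinct values, no ties
    a <- v[1:m]; b <- v[-(1:m)]
    got <- mann_whitney_u(a, b)
    expect_true(got$exact)
    expect_equal(got$p, oracle_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation kicks in beyond the crossover", {
  x <- c(1, 5, 7); y <- c(2, 2, 9)   # tied values force the approximation
  expect_false(mann_whitney_u(x, y)$exact)
  set.seed(31)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  exact <- mann_whitney_u(a, b, exact_max = 20)
  approx <- mann_whitney_u(a, b, exact_max = 0)
  expect_true(exact$exact); expect_false(approx$exact)
  expect_lt(abs(exact$p - approx$p), 0.02)   # crossover agreement
  ident <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p, 1)
})

test_that("Mann-Whitney detects a two-SD shift at n = 20 per group", {
  set.seed(17)
  hits <- 0L
  for (i in 1:200) {
    p <- mann_whitney_u(rnorm(20), rnorm(20, 2))$p
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / 200, 0.95)
})

test_that("signed-rank exact branch reproduces the enumeration oracle", {
  # all five differences positive: P(V >= 15) = 1/32, doubled
  res <- wilcoxon_signed_rank(c(0.5, 1, 1.5, 2, 2.5))
  expect_equal(res$W, 15)
  expect_equal(res$p, 2 / 32, tolerance = 1e-12)
  expect_equal(res$p, oracle_wsr_p(c(0.5, 1, 1.5, 2, 2.5)),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    got <- wilcoxon_signed_rank(d)
    expect_true(got$exact)
    expect_equal(got$p, oracle_wsr_p(d), tolerance = 1e-12)
  }
  # symmetric +/- pairs: maximal two-sided p
  expect_equal(wilcoxon_signed_rank(c(-2, 2, -1, 1))$p, 1,
               tolerance = 0.08)
  expect_warning(z <- wilcoxon_signed_rank(c(0, 0)), "zero")
  expect_true(is.na(z$p))
  set.seed(43)
  d <- rnorm(15)
  expect_lt(abs(wilcoxon_signed_rank(d, exact_max = 15)$p -
                  wilcoxon_signed_rank(d, exact_max = 0)$p), 0.02)
})

# ---- regression -------------------------------------------------------

test_that("linear regression recovers exact and random-data fits", {
  x <- 1:10
  fit <- suppressWarnings(linear_regression(x, 2 * x + 1))  # exact fit
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # normal-equation oracle
  set.seed(6)
  xr <- rnorm(40); yr <- 1.3 * xr + rnorm(40)
  f2 <- linear_regression(xr, yr)
  beta <- solve(crossprod(cbind(1, xr)), crossprod(cbind(1, xr), yr))
  expect_equal(f2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f2$slope, beta[2], tolerance = 1e-10)
  set.seed(7)
  noise <- linear_regression(rnorm(200), rnorm(200))
  expect_lt(noise$r_squared, 0.1)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "constant")
})

test_that("slope comparison is the ANCOVA interaction F", {
  # same exact line in both groups: no slope difference signal
  same <- suppressWarnings({
    fa <- linear_regression(1:10, 2 * (1:10) + 1)
    fb <- linear_regression(2:11, 2 * (2:11) + 1)
    compare_slopes(fa, fb)
  })
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # df anchor: n_a = n_b = 24 gives denominator df 44
  set.seed(10)
  xa <- rnorm(24); ya <- xa + rnorm(24)
  xb <- rnorm(24); yb <- 1.5 * xb + rnorm(24)
  cmp <- compare_slopes(linear_regression(xa, ya),
                        linear_regression(xb, yb))
  expect_equal(cmp$df1, 1); expect_equal(cmp$df2, 44)
  # from-scratch design-matrix oracle
  X_full <- cbind(1, c(xa, xb), rep(c(0, 1), each = 24),
                  c(xa, xb) * rep(c(0, 1), each = 24))
  y <- c(ya, yb)
  sse <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  sse_full <- sse(X_full); sse_red <- sse(X_full[, 1:3])
  expect_equal(cmp$F, (sse_red - sse_full) / (sse_full / 44),
               tolerance = 1e-10)
})

test_that("slope comparison detects slopes three SE apart", {
  set.seed(12)
  hits <- 0L
  for (i in 1:60) {
    xa <- runif(30); xb <- runif(30)
    # slope SE is about sigma / (sd(x) sqrt(n)); separation about 3 SE
    se <- 1 / (sd(xa) * sqrt(30))
    ya <- xa + rnorm(30); yb <- (1 + 3 * sqrt(2) * se) * xb + rnorm(30)
    cmp <- compare_slopes(linear_regression(xa, ya),
                          linear_regression(xb, yb))
    hits <- hits + (cmp$p < 0.05)
  }
  expect_gt(hits / 60, 0.5)
})

# ---- frequency-distribution fits -------------------------------------

test_that("Gaussian histogram fit recovers a known mode", {
  set.seed(20)
  areas <- rnorm(5000, mean = 150, sd = 30)
  fit <- fit_size_distribution(areas, bin_width = 10)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters["mode"]), 150, tolerance = 0.02)
  expect_gt(fit$r_squared, 0.95)
  expect_error(fit_size_distribution(rnorm(20)), "at least 50")
})

test_that("log-normal form fits right-skewed areas", {
  set.seed(24)
  areas <- rlnorm(3000, log(140), 0.25)
  fit <- fit_size_distribution(areas, bin_width = 10, form = "lognormal")
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters["mode"]), 140, tolerance = 0.06)
})

test_that("distribution comparison: identical samples give F = 0, offset ones differ", {
  set.seed(22)
  a <- rnorm(500, 160, 25)
  same <- compare_size_distributions(a, a, bin_width = 10)
  expect_equal(same$F, 0, tolerance = 1e-6)
  b <- rnorm(500, 160 * 0.85, 25)   # 15 percent smaller population
  diffr <- compare_size_distributions(a, b, bin_width = 10)
  expect_lt(diffr$p, 0.001)
})
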