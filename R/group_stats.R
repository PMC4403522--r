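#' Aggregate per-cell profiles to per-animal rows
#'
#' The experimental unit for arbor comparisons is the animal: cell
#' profiles (Sholl shells or branch orders) are first averaged within
#' animal at each level.  A cell whose arbor does not reach a level
#' contributes the true value 0 there (its cable/branch count at that
#' level is zero, not missing), so the resulting matrix is complete by
#' construction.
#'
#' @param data long data.frame with columns `cell_id`, `animal_id`,
#'   `genotype`, `level` (integer shell index or branch order), `value`.
#' @param fill value recorded for levels a cell does not reach
#'   (default 0).
#' @param max_level optionally truncate all profiles to `level <=
#'   max_level`.
#' @return A complete long data.frame of class `profile_matrix` with
#'   columns `unit`, `genotype`, `level`, `value` (one row per animal x
#'   level).
#' @export
aggregate_per_animal <- function(data, fill = 0, max_level = NULL) {
  stopifnot(all(c("cell_id", "animal_id", "genotype", "level", "value")
                %in% names(data)))
  if (!is.null(max_level)) data <- data[data$level <= max_level, ]
  levels_all <- sort(unique(data$level))
  cells <- unique(data[, c("cell_id", "animal_id", "genotype")])
  if (any(table(cells$cell_id) > 1L))
    stop("a cell_id maps to more than one animal/genotype")
  grid <- merge(cells, data.frame(level = levels_all), by = NULL)
  full <- merge(grid, data[, c("cell_id", "level", "value")],
                by = c("cell_id", "level"), all.x = TRUE)
  full$value[is.na(full$value)] <- fill
  agg <- aggregate(value ~ animal_id + genotype + level, data = full,
                   FUN = mean)
  n_cells <- aggregate(cell_id ~ animal_id, data = cells, FUN = length)
  if (any(n_cells$cell_id == 0L))
    warning("animal with no cells dropped")
  out <- data.frame(unit = agg$animal_id, genotype = agg$genotype,
                    level = agg$level, value = agg$value)
  out <- out[order(out$unit, out$level), ]
  rownames(out) <- NULL
  structure(out, class = c("profile_matrix", "data.frame"))
}

.check_profile_matrix <- function(pm) {
  stopifnot(all(c("unit", "genotype", "level", "value") %in% names(pm)))
  tab <- table(pm$unit, pm$level)
  if (any(tab != 1L))
    stop("profile matrix is incomplete; truncate to the common level ",
         "range (see aggregate_per_animal(max_level = ...))")
  g_per_unit <- tapply(pm$genotype, pm$unit, function(g) length(unique(g)))
  if (any(g_per_unit != 1L)) stop("a unit maps to more than one genotype")
  invisible(pm)
}

#' Mixed two-way repeated-measures ANOVA with Bonferroni post-tests
#'
#' The design used for all parameters assessed across Sholl radii or
#' branch orders: genotype is a between-unit factor, level (radius or
#' order) a within-unit factor, and units (animals) are the random
#' blocks.  Fitted with [stats::aov()] error strata
#' (`Error(unit/level)`): genotype is tested against between-unit
#' variation, level and the genotype x level interaction against the
#' within-unit residual.  Pairwise genotype contrasts at each level are
#' two-sample pooled-variance t tests on unit values, Bonferroni
#' adjusted over the whole family (levels x genotype pairs) and capped
#' at 1.  No sphericity correction is applied by default.
#'
#' @param pm a complete [aggregate_per_animal()] profile matrix (or any
#'   data.frame with `unit`, `genotype`, `level`, `value`).
#' @param gg_correct apply a Greenhouse-Geisser epsilon correction to
#'   the within-unit df (default `FALSE`).
#' @param posthoc compute the per-level pairwise contrasts (default
#'   `TRUE`; disable in simulation loops that only need the F table).
#' @return A list of class `rm_anova`: `anova_table` (effect, df1, df2,
#'   F, p) and `posthoc` (level, pair, mean difference, t, df, raw and
#'   Bonferroni-adjusted p).
#' @export
rm_anova <- function(pm, gg_correct = FALSE, posthoc = TRUE) {
  .check_profile_matrix(pm)
  d <- data.frame(unit = factor(pm$unit), genotype = factor(pm$genotype),
                  level = factor(pm$level), value = pm$value)
  if (nlevels(d$genotype) < 2L || nlevels(d$level) < 2L)
    stop("need at least two genotypes and two levels")
  fit <- aov(value ~ genotype * level + Error(unit / level), data = d)
  s <- summary(fit)
  between <- s[["Error: unit"]][[1L]]
  within <- s[["Error: unit:level"]][[1L]]
  rn <- function(x) trimws(rownames(x))
  tab <- data.frame(
    effect = c("genotype", "level", "genotype:level"),
    df1 = c(between[rn(between) == "genotype", "Df"],
            within[rn(within) == "level", "Df"],
            within[rn(within) == "genotype:level", "Df"]),
    df2 = c(between[rn(between) == "Residuals", "Df"],
            rep(within[rn(within) == "Residuals", "Df"], 2L)),
    F = c(between[rn(between) == "genotype", "F value"],
          within[rn(within) == "level", "F value"],
          within[rn(within) == "genotype:level", "F value"]),
    p = c(between[rn(between) == "genotype", "Pr(>F)"],
          within[rn(within) == "level", "Pr(>F)"],
          within[rn(within) == "genotype:level", "Pr(>F)"]))
  if (gg_correct) {
    eps <- .gg_epsilon(d)
    w <- tab$effect != "genotype"
    tab$df1[w] <- tab$df1[w] * eps
    tab$df2[w] <- tab$df2[w] * eps
    tab$p[w] <- pf(tab$F[w], tab$df1[w], tab$df2[w], lower.tail = FALSE)
  }
  lev <- levels(d$level)
  gen <- levels(d$genotype)
  pairs <- utils::combn(gen, 2L, simplify = FALSE)
  family <- length(lev) * length(pairs)
  if (!posthoc)
    return(structure(list(anova_table = tab, posthoc = NULL,
                          family_size = family), class = "rm_anova"))
  ph <- list()
  for (lv in lev) for (pr in pairs) {
    a <- d$value[d$level == lv & d$genotype == pr[1L]]
    b <- d$value[d$level == lv & d$genotype == pr[2L]]
    ct <- .pooled_t(a, b)
    ph[[length(ph) + 1L]] <- data.frame(
      level = lv, group1 = pr[1L], group2 = pr[2L], diff = ct$diff,
      t = ct$t, df = ct$df, p_raw = ct$p,
      p_adj = min(1, ct$p * family))
  }
  structure(list(anova_table = tab, posthoc = do.call(rbind, ph),
                 family_size = family),
            class = "rm_anova")
}

# Greenhouse-Geisser epsilon from the pooled within-genotype covariance
# of the unit x level matrix
.gg_epsilon <- function(d) {
  wide <- tapply(d$value, list(d$unit, d$level), identity)
  gmap <- tapply(as.character(d$genotype), d$unit, `[`, 1L)
  covs <- lapply(split(as.data.frame(wide), gmap[rownames(wide)]),
                 function(w) stats::cov(as.matrix(w)))
  S <- Reduce(`+`, covs) / length(covs)
  k <- ncol(S)
  num <- (k * mean(diag(S)) - mean(S))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) +
                      k^2 * mean(S)^2)
  max(1 / (k - 1), min(1, num / den))
}

#' One-way ANOVA on group scalars
#'
#' Standard between/within decomposition, e.g. for primary dendrite
#' counts or maximum radial distance per animal across genotypes.
#'
#' @param groups named list of numeric vectors (one per group, each with
#'   at least two values).
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least two values")
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups) %||%
                                       seq_along(groups),
                                     lengths(groups))))
  a <- anova(aov(value ~ group, data = d))
  list(F = a[1, "F value"], df1 = a[1, "Df"], df2 = a[2, "Df"],
       p = a[1, "Pr(>F)"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mann-Whitney U test (two-sample rank test)
#'
#' Two-sided test for between-animal comparisons of soma and nuclear
#' areas.  Uses the exact null distribution when the combined sample
#' size is at most `exact_max` and there are no ties, and the
#' tie-corrected normal approximation (with continuity correction)
#' otherwise.
#'
#' @param a,b numeric samples.
#' @param exact_max combined-size threshold for the exact branch
#'   (default 20).
#' @return A list with `U` (statistic for sample `a`), `p` (two-sided)
#'   and `exact` (logical, which branch was used).
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- any(duplicated(c(a, b)))
  use_exact <- (length(a) + length(b)) <= exact_max && !ties
  res <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE))
  list(U = unname(res$statistic), p = res$p.value, exact = use_exact)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided paired test for within-animal genotype comparisons.  Zero
#' differences are dropped; the exact distribution is used for up to
#' `exact_max` nonzero differences without tied magnitudes, the normal
#' approximation beyond.
#'
#' @param d numeric vector of paired differences (or supply `x` and `y`
#'   via `d = x - y`).
#' @param exact_max sample-size threshold for the exact branch
#'   (default 15).
#' @return A list with `W` (positive-rank sum), `p` (two-sided),
#'   `n_used` (nonzero differences) and `exact`.  `NA` p with a warning
#'   when all differences are zero.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 15) {
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all differences are zero; test undefined")
    return(list(W = NA_real_, p = NA_real_, n_used = 0L, exact = NA))
  }
  ties <- any(duplicated(abs(d)))
  use_exact <- length(d) <= exact_max && !ties
  res <- suppressWarnings(
    wilcox.test(d, exact = use_exact, correct = TRUE))
  list(W = unname(res$statistic), p = res$p.value,
       n_used = length(d), exact = use_exact)
}

#' Simple linear regression
#'
#' Least-squares fit with the two-sided test of slope = 0, as used for
#' size-versus-age and size-versus-XCI relationships.
#'
#' @param x,y numeric vectors (at least 3 points; `x` not constant).
#' @return A list of class `size_regression`: `slope`, `intercept`,
#'   `r_squared`, `p`, `df_residual`, and the data (`x`, `y`) for later
#'   slope comparison.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points")
  if (var(x) == 0) stop("x is constant; slope undefined")
  fit <- lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = s$r.squared,
                 p = s$coefficients[2L, 4L],
                 df_residual = fit$df.residual,
                 x = x, y = y),
            class = "size_regression")
}

#' Test equality of two regression slopes
#'
#' Pooled-model interaction F test (textbook ANCOVA): both datasets are
#' fitted jointly with a group term and a slope x group interaction;
#' the interaction F with df (1, n_a + n_b - 4) tests slope equality.
#'
#' @param fit_a,fit_b [linear_regression()] results carrying their data.
#' @return A list with `F`, `df1`, `df2`, `p`, and the two slopes.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "size_regression"),
            inherits(fit_b, "size_regression"))
  d <- data.frame(x = c(fit_a$x, fit_b$x), y = c(fit_a$y, fit_b$y),
                  g = factor(rep(c("a", "b"),
                                 c(length(fit_a$x), length(fit_b$x)))))
  a <- anova(lm(y ~ x * g, data = d))
  Fv <- a["x:g", "F value"]
  pv <- a["x:g", "Pr(>F)"]
  if (a["Residuals", "Sum Sq"] < 1e-12 && a["x:g", "Sum Sq"] < 1e-12) {
    Fv <- 0; pv <- 1         # both datasets on one exact line
  }
  list(F = Fv, df1 = a["x:g", "Df"], df2 = a["Residuals", "Df"],
       p = pv, slope_a = fit_a$slope, slope_b = fit_b$slope)
}

.size_hist <- function(areas, bin_width) {
  breaks <- seq(floor(min(areas) / bin_width) * bin_width,
                ceiling(max(areas) / bin_width) * bin_width,
                by = bin_width)
  h <- graphics::hist(areas, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, freq = 100 * h$counts / length(areas))
}

.curve_fun <- function(form) {
  switch(form,
         gaussian = function(x, amplitude, mode, width)
           amplitude * exp(-(x - mode)^2 / (2 * width^2)),
         lognormal = function(x, amplitude, mode, width)
           amplitude * exp(-(log(x) - log(mode))^2 / (2 * width^2)))
}

#' Fit a curve to a size frequency distribution
#'
#' Bins areas at a fixed width, expresses bin counts as percentage of
#' cells, and fits a bell-shaped curve by least squares
#' ([minpack.lm::nlsLM()]).  The default Gaussian form
#' `A exp(-(x - m)^2 / (2 s^2))` can be swapped for a log-normal shape
#' (Gaussian in log-area), which better matches right-skewed area
#' distributions.
#'
#' @param areas numeric vector of areas (at least 50 values).
#' @param bin_width histogram bin width in square micrometres
#'   (default 10).
#' @param form `"gaussian"` (default) or `"lognormal"`.
#' @return A list of class `size_distribution_fit`: `parameters`
#'   (amplitude, mode, width), `r_squared`, `converged`, `form`,
#'   `bin_width`, and the binned data (`hist`).  On non-convergence,
#'   `converged = FALSE` with the error message in `diagnostics`.
#' @export
fit_size_distribution <- function(areas, bin_width = 10,
                                  form = c("gaussian", "lognormal")) {
  form <- match.arg(form)
  if (length(areas) < 50L) stop("need at least 50 areas")
  h <- .size_hist(areas, bin_width)
  f <- .curve_fun(form)
  start <- list(amplitude = max(h$freq),
                mode = h$mid[which.max(h$freq)],
                width = if (form == "gaussian") sd(areas) else
                  sd(log(areas)))
  fit <- tryCatch(
    minpack.lm::nlsLM(freq ~ f(mid, amplitude, mode, width),
                      data = h, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(parameters = NULL, r_squared = NA_real_,
                          converged = FALSE, form = form,
                          bin_width = bin_width, hist = h,
                          diagnostics = conditionMessage(fit)),
                     class = "size_distribution_fit"))
  pars <- coef(fit)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((h$freq - mean(h$freq))^2)
  structure(list(parameters = pars,
                 r_squared = 1 - ss_res / ss_tot,
                 converged = TRUE, form = form, bin_width = bin_width,
                 hist = h, diagnostics = NULL),
            class = "size_distribution_fit")
}

#' Compare two size frequency distributions
#'
#' Extra-sum-of-squares F test: both histograms (shared breaks,
#' percentage scale) are fitted with one shared curve versus separate
#' curves per group; a large F means the two populations' size
#' distributions differ in shape or location.
#'
#' @param areas_a,areas_b numeric vectors of areas.
#' @inheritParams fit_size_distribution
#' @return A list with `F`, `df1`, `df2`, `p`, and the separate fits.
#' @export
compare_size_distributions <- function(areas_a, areas_b, bin_width = 10,
                                       form = c("gaussian", "lognormal")) {
  form <- match.arg(form)
  f <- .curve_fun(form)
  lo <- floor(min(areas_a, areas_b) / bin_width) * bin_width
  hi <- ceiling(max(areas_a, areas_b) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  hb <- function(v) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, freq = 100 * h$counts / length(v))
  }
  ha <- hb(areas_a); hbb <- hb(areas_b)
  both <- rbind(ha, hbb)
  fit1 <- function(h, start) minpack.lm::nlsLM(
    freq ~ f(mid, amplitude, mode, width), data = h, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  start_of <- function(v, h) list(
    amplitude = max(h$freq), mode = h$mid[which.max(h$freq)],
    width = if (form == "gaussian") sd(v) else sd(log(v)))
  fa <- fit1(ha, start_of(areas_a, ha))
  fb <- fit1(hbb, start_of(areas_b, hbb))
  fs <- fit1(both, start_of(c(areas_a, areas_b), both))
  ss_sep <- sum(resid(fa)^2) + sum(resid(fb)^2)
  ss_shared <- sum(resid(fs)^2)
  df_sep <- nrow(both) - 6L
  df1 <- 3L
  Fv <- max(0, ((ss_shared - ss_sep) / df1) / (ss_sep / df_sep))
  list(F = Fv, df1 = df1, df2 = df_sep,
       p = pf(Fv, df1, df_sep, lower.tail = FALSE),
       fit_a = fa, fit_b = fb)
}
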