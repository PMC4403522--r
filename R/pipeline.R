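# pooled-variance two-sample t test (shared by post-tests and contrasts)
.pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- mean(a) - mean(b)
  tval <- if (is.finite(se) && se > 0) diff / se else 0
  df <- na + nb - 2L
  list(diff = diff, t = tval, df = df,
       p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}

#' Morphometry tables for a set of neurons
#'
#' Runs the per-neuron morphometry over a list of trees and returns the
#' three tidy tables the statistics stage consumes.
#'
#' @param trees list of [neuron_tree()] objects.
#' @param shell_width Sholl shell width in micrometres.
#' @return A list with `sholl` (one row per cell x shell), `orders`
#'   (one row per cell x branch order) and `summaries` (one row per
#'   cell, from [neuron_summary()]).
#' @export
summarize_arbors <- function(trees, shell_width = 10) {
  sholl <- list(); orders <- list(); summaries <- list()
  for (tr in trees) {
    sp <- sholl_profile(tr, shell_width)
    bo <- branch_order_profile(tr)
    id <- tr$cell_id
    sholl[[id]] <- cbind(cell_id = id, animal_id = tr$animal_id,
                         genotype = tr$genotype, as.data.frame(sp))
    orders[[id]] <- cbind(cell_id = id, animal_id = tr$animal_id,
                          genotype = tr$genotype, as.data.frame(bo))
    summaries[[id]] <- neuron_summary(tr)
  }
  list(sholl = do.call(rbind, c(sholl, make.row.names = FALSE)),
       orders = do.call(rbind, c(orders, make.row.names = FALSE)),
       summaries = do.call(rbind, c(summaries, make.row.names = FALSE)))
}

#' Genotype contrasts on whole-cell arbor parameters
#'
#' For each scalar parameter reports the per-genotype means, a one-way
#' ANOVA across all genotypes present, and the pooled-t MeCP2- versus
#' MeCP2+ contrast.  With `unit = "animal"` (the conservative default
#' in [run_pipeline()]) cells are first averaged within animal and
#' animals are the error units; with `unit = "cell"` individual cells
#' are the units, mirroring analyses whose error df are cell-based.
#'
#' @param summaries the `summaries` table of [summarize_arbors()].
#' @param parameters which columns to test.
#' @param unit experimental unit for the error term.
#' @return A data.frame, one row per parameter.
#' @export
arbor_contrasts <- function(summaries,
                            parameters = c("total_length_um",
                                           "n_branch_points",
                                           "n_primary",
                                           "mean_branch_length_um",
                                           "max_radial_distance_um"),
                            unit = c("animal", "cell")) {
  unit <- match.arg(unit)
  rows <- list()
  for (par in parameters) {
    if (unit == "animal") {
      am <- aggregate(summaries[[par]],
                      by = list(animal_id = summaries$animal_id,
                                genotype = summaries$genotype), FUN = mean)
      groups <- split(am$x, am$genotype)
    } else {
      groups <- split(summaries[[par]], summaries$genotype)
    }
    ow <- if (length(groups) >= 2L && all(lengths(groups) >= 2L))
      one_way_anova(groups) else list(F = NA_real_, p = NA_real_)
    ct <- if (all(c("MeCP2-", "MeCP2+") %in% names(groups)))
      .pooled_t(groups[["MeCP2-"]], groups[["MeCP2+"]])
    else list(diff = NA_real_, t = NA_real_, p = NA_real_)
    rows[[par]] <- data.frame(
      parameter = par,
      mean_wt = if ("WT" %in% names(groups)) mean(groups[["WT"]])
                else NA_real_,
      mean_plus = if ("MeCP2+" %in% names(groups))
        mean(groups[["MeCP2+"]]) else NA_real_,
      mean_minus = if ("MeCP2-" %in% names(groups))
        mean(groups[["MeCP2-"]]) else NA_real_,
      anova_F = ow$F, anova_p = ow$p,
      minus_vs_plus_diff = ct$diff, minus_vs_plus_p = ct$p)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> morphometry -> sizes ->
#' stats -> report pipeline.  Values in a YAML `file` override the
#' defaults and named arguments override the file.
#'
#' @param file optional YAML file of settings.
#' @param ... settings overriding defaults and file: `input_dir` (read
#'   an existing cohort instead of simulating), `out_dir`, `seed`,
#'   `shell_width`, `max_branch_order` (truncation for order-profile
#'   statistics), `exact_max_u`, `exact_max_w` (rank-test exact
#'   thresholds), `distribution_form` (`"gaussian"`/`"lognormal"`),
#'   `pixel_size_um`, `unit` (`"animal"` or `"cell"`),
#'   `normalization` (`"animal"` or `"slice"`), plus `n_animals`,
#'   `cells_per_animal`, `n_size_animals`, `n_wt_size_animals`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(input_dir = NULL, out_dir = "results", seed = 1L,
              shell_width = 10, max_branch_order = 6L,
              exact_max_u = 20L, exact_max_w = 15L,
              distribution_form = "gaussian", pixel_size_um = 1,
              unit = "animal", normalization = "animal",
              n_animals = 5L, cells_per_animal = c(16L, 31L),
              n_size_animals = 24L, n_wt_size_animals = 10L)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    cfg[names(from_file)] <- from_file
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$shell_width > 0)
  structure(cfg, class = "run_config")
}

.read_cohort_dir <- function(dir) {
  meta <- read.csv(file.path(dir, "reconstruction_metadata.csv"))
  trees <- lapply(seq_len(nrow(meta)), function(i)
    read_swc(file.path(dir, "swc", paste0(meta$cell_id[i], ".swc")),
             cell_id = meta$cell_id[i], animal_id = meta$animal_id[i],
             genotype = meta$genotype[i]))
  names(trees) <- meta$cell_id
  rd <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) read.csv(p) else NULL
  }
  list(trees = trees, reconstruction_metadata = meta,
       outlines = rd("outlines.csv"), size_metadata = rd("size_metadata.csv"),
       animals = rd("animals.csv"))
}

.fmt_p <- function(p) ifelse(p < 1e-4, "p < 0.0001", sprintf("p = %.4g", p))

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> morphometry -> sizes -> stats -> report.
#' Without `input_dir` a cohort is simulated from [default_presets()]
#' and written under `out_dir/simulated` so the analysis stages consume
#' the same file formats as real data.  Outputs under `out_dir`: tidy
#' per-neuron profile tables, per-animal summaries, an exclusions table
#' (every input cell appears either there or in the summaries), test
#' tables per statistics family, a plain-text `report.txt`, and
#' `run_info.yml` echoing the effective configuration and seed.
#' Re-running with the same configuration reproduces every output
#' byte-identically.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # -- simulate ------------------------------------------------------
  if (is.null(config$input_dir)) {
    spec <- cohort_spec(n_animals = config$n_animals,
                        cells_per_animal = config$cells_per_animal,
                        n_size_animals = config$n_size_animals,
                        n_wt_size_animals = config$n_wt_size_animals,
                        seed = config$seed)
    cohort <- generate_cohort(default_presets(), spec)
    write_cohort(cohort, file.path(out, "simulated"))
    input_dir <- file.path(out, "simulated")
  } else input_dir <- config$input_dir
  data <- tryCatch(.read_cohort_dir(input_dir), error = function(e)
    stop("stage 'load' failed: ", conditionMessage(e)))

  # -- morphometry ---------------------------------------------------
  meta <- filter_reconstructions(data$reconstruction_metadata)
  kept <- meta$cell_id[meta$keep]
  exclusions <- meta[!meta$keep, c("cell_id", "animal_id", "reason")]
  write.csv(exclusions, file.path(out, "exclusions.csv"),
            row.names = FALSE)
  arb <- summarize_arbors(data$trees[kept], config$shell_width)
  write.csv(arb$sholl, file.path(out, "sholl_profiles.csv"),
            row.names = FALSE)
  write.csv(arb$orders, file.path(out, "branch_order_profiles.csv"),
            row.names = FALSE)
  write.csv(arb$summaries, file.path(out, "cell_summaries.csv"),
            row.names = FALSE)

  # -- stats: arbors -------------------------------------------------
  long_of <- function(df, value_col) data.frame(
    cell_id = df$cell_id, animal_id = df$animal_id,
    genotype = df$genotype,
    level = if ("shell" %in% names(df)) df$shell else df$order,
    value = df[[value_col]])
  rm_tests <- list(
    sholl_length = rm_anova(aggregate_per_animal(
      long_of(arb$sholl, "length_um"))))
  # cumulative profiles need carry-forward fill (a cell that stops at
  # shell k keeps its total beyond k), handled separately:
  cum <- long_of(arb$sholl, "cumulative_length_um")
  rm_tests$sholl_cumulative_length <-
    rm_anova(.cumulative_profile_matrix(cum))
  cbp <- long_of(arb$sholl, "n_branch_points")
  cbp$value <- stats::ave(cbp$value, cbp$cell_id, FUN = cumsum)
  rm_tests$sholl_cumulative_branch_points <-
    rm_anova(.cumulative_profile_matrix(cbp))
  ord_len <- aggregate_per_animal(long_of(arb$orders, "total_length_um"),
                                  max_level = config$max_branch_order)
  rm_tests$order_length <- rm_anova(ord_len)
  ord_n <- aggregate_per_animal(long_of(arb$orders, "n_branches"),
                                max_level = config$max_branch_order)
  rm_tests$order_branches <- rm_anova(ord_n)
  anova_rows <- do.call(rbind, lapply(names(rm_tests), function(nm)
    cbind(family = nm, rm_tests[[nm]]$anova_table)))
  write.csv(anova_rows, file.path(out, "rm_anova_tests.csv"),
            row.names = FALSE)
  contrasts <- arbor_contrasts(arb$summaries)
  write.csv(contrasts, file.path(out, "arbor_contrasts.csv"),
            row.names = FALSE)

  # -- sizes ---------------------------------------------------------
  size_results <- NULL
  if (!is.null(data$size_metadata)) {
    sizes <- cell_size_table(data$outlines, data$size_metadata,
                             pixel_size_um = config$pixel_size_um)
    inc <- apply_inclusion(sizes)
    write.csv(inc$excluded, file.path(out, "size_exclusions.csv"),
              row.names = FALSE)
    animals <- .summarize_size_animals(inc$included, data$animals,
                                       by = config$normalization)
    write.csv(animals, file.path(out, "animal_summaries.csv"),
              row.names = FALSE)
    size_results <- .size_stats(inc$included, animals, config)
    write.csv(size_results$tests, file.path(out, "size_tests.csv"),
              row.names = FALSE)
  } else animals <- NULL

  # -- report --------------------------------------------------------
  report <- .write_report(out, contrasts, rm_tests, size_results, config)
  yaml::write_yaml(list(package_version =
                          as.character(utils::packageVersion("mosaicmorph")),
                        r_version = as.character(getRversion()),
                        seed = config$seed,
                        config = unclass(config)),
                   file.path(out, "run_info.yml"))
  invisible(list(summaries = arb$summaries, contrasts = contrasts,
                 rm_tests = rm_tests, animals = animals,
                 size_tests = size_results$tests,
                 exclusions = exclusions, report = report))
}

# complete a cumulative per-cell profile by carrying the last value
# forward (a cell that stops at shell k keeps its total beyond k), then
# aggregate to animal rows
.cumulative_profile_matrix <- function(long) {
  levels_all <- sort(unique(long$level))
  per_cell <- split(long, long$cell_id)
  filled <- lapply(per_cell, function(d) {
    d <- d[order(d$level), ]
    idx <- findInterval(levels_all, d$level)
    data.frame(cell_id = d$cell_id[1L], animal_id = d$animal_id[1L],
               genotype = d$genotype[1L], level = levels_all,
               value = c(0, d$value)[idx + 1L])
  })
  aggregate_per_animal(do.call(rbind, filled))
}

.summarize_size_animals <- function(records, animals, by = "animal") {
  rows <- list()
  for (aid in unique(records$animal_id)) {
    r <- records[records$animal_id == aid, ]
    is_het <- any(r$genotype %in% c("MeCP2+", "MeCP2-"))
    xci <- if (is_het) xci_fraction(r$genotype) else NA_real_
    norm <- if (is_het && all(c("MeCP2+", "MeCP2-") %in% r$genotype))
      normalize_within_animal(r, by = by)
    else list(soma_ratio = NA_real_, nucleus_ratio = NA_real_)
    gmean <- function(g, col) if (any(r$genotype == g))
      mean(r[[col]][r$genotype == g]) else NA_real_
    rows[[aid]] <- data.frame(
      animal_id = aid, n_cells = nrow(r), xci_fraction_minus = xci,
      soma_wt = gmean("WT", "soma_area_um2"),
      soma_plus = gmean("MeCP2+", "soma_area_um2"),
      soma_minus = gmean("MeCP2-", "soma_area_um2"),
      nucleus_wt = gmean("WT", "nucleus_area_um2"),
      nucleus_plus = gmean("MeCP2+", "nucleus_area_um2"),
      nucleus_minus = gmean("MeCP2-", "nucleus_area_um2"),
      normalized_minus_soma = norm$soma_ratio,
      normalized_minus_nucleus = norm$nucleus_ratio)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(animals))
    out <- merge(out, animals[, c("animal_id", "age_months",
                                  "phenotype_score")],
                 by = "animal_id", all.x = TRUE)
  out
}

.size_stats <- function(records, animals, config) {
  het <- animals[!is.na(animals$xci_fraction_minus), ]
  tests <- list()
  add <- function(name, statistic, value, p, extra = NA_character_)
    tests[[length(tests) + 1L]] <<- data.frame(
      test = name, statistic = statistic, value = value, p = p,
      note = extra)
  # within-animal paired genotype comparison
  ok <- complete.cases(het$soma_plus, het$soma_minus)
  ws <- wilcoxon_signed_rank(het$soma_minus[ok] - het$soma_plus[ok],
                             exact_max = config$exact_max_w)
  add("soma_minus_vs_plus_paired", "W", ws$W, ws$p)
  wn <- wilcoxon_signed_rank(het$nucleus_minus[ok] - het$nucleus_plus[ok],
                             exact_max = config$exact_max_w)
  add("nucleus_minus_vs_plus_paired", "W", wn$W, wn$p)
  # between-animal WT vs MeCP2+ (present when WT animals simulated)
  wt <- animals$soma_wt[!is.na(animals$soma_wt)]
  if (length(wt) >= 2L) {
    mw <- mann_whitney_u(wt, het$soma_plus[!is.na(het$soma_plus)],
                         exact_max = config$exact_max_u)
    add("soma_wt_vs_plus", "U", mw$U, mw$p)
  }
  # normalised ratio vs XCI fraction
  fits <- list()
  for (what in c("normalized_minus_soma", "normalized_minus_nucleus")) {
    okx <- complete.cases(het$xci_fraction_minus, het[[what]])
    fit <- linear_regression(het$xci_fraction_minus[okx], het[[what]][okx])
    fits[[what]] <- fit
    add(paste0(what, "_vs_xci"), "slope", fit$slope, fit$p,
        sprintf("R2 = %.3f", fit$r_squared))
  }
  # soma area as predictor of nucleus area, slopes compared by genotype
  slope_cmp <- NULL
  pl <- records[records$genotype == "MeCP2+", ]
  mi <- records[records$genotype == "MeCP2-", ]
  if (nrow(pl) >= 3L && nrow(mi) >= 3L) {
    fp <- linear_regression(pl$soma_area_um2, pl$nucleus_area_um2)
    fm <- linear_regression(mi$soma_area_um2, mi$nucleus_area_um2)
    slope_cmp <- compare_slopes(fm, fp)
    add("nucleus_on_soma_slope_equality", "F", slope_cmp$F, slope_cmp$p,
        sprintf("df = (%d, %d)", slope_cmp$df1, slope_cmp$df2))
    # frequency-distribution comparison
    if (nrow(pl) >= 50L && nrow(mi) >= 50L) {
      cmp <- compare_size_distributions(pl$soma_area_um2, mi$soma_area_um2,
                                        form = config$distribution_form)
      add("soma_size_distributions", "F", cmp$F, cmp$p,
          sprintf("df = (%d, %d)", cmp$df1, cmp$df2))
    }
  }
  list(tests = do.call(rbind, c(tests, make.row.names = FALSE)),
       xci_fits = fits, slope_cmp = slope_cmp)
}

.write_report <- function(out, contrasts, rm_tests, size_results, config) {
  ln <- character()
  say <- function(...) ln <<- c(ln, sprintf(...))
  say("mosaicmorph pipeline report (seed %d)", config$seed)
  say("=========================================")
  say("")
  say("Arbor contrasts (animal means; MeCP2- vs MeCP2+):")
  for (i in seq_len(nrow(contrasts))) {
    r <- contrasts[i, ]
    say("  %-24s WT %8.2f  MeCP2+ %8.2f  MeCP2- %8.2f  diff %8.2f (%s)",
        r$parameter, r$mean_wt, r$mean_plus, r$mean_minus,
        r$minus_vs_plus_diff, .fmt_p(r$minus_vs_plus_p))
  }
  say("")
  say("Repeated-measures ANOVA (genotype x level):")
  for (nm in names(rm_tests)) {
    tb <- rm_tests[[nm]]$anova_table
    ix <- tb$effect == "genotype:level"
    say("  %-32s interaction F(%d,%d) = %.2f, %s", nm,
        tb$df1[ix], tb$df2[ix], tb$F[ix], .fmt_p(tb$p[ix]))
  }
  if (!is.null(size_results)) {
    say("")
    say("Cell size tests:")
    for (i in seq_len(nrow(size_results$tests))) {
      r <- size_results$tests[i, ]
      say("  %-36s %s = %10.4f, %s", r$test, r$statistic, r$value,
          .fmt_p(r$p))
    }
  }
  writeLines(ln, file.path(out, "report.txt"))
  ln
}
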