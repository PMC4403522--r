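test_that("arbor generation is deterministic given (preset, seed)", {
  p <- default_presets()[["MeCP2+"]]
  a <- generate_arbor(p, seed = 123)
  b <- generate_arbor(p, seed = 123)
  expect_identical(write_swc(a), write_swc(b))   # byte-identical SWC
  c2 <- generate_arbor(p, seed = 124)
  expect_false(identical(write_swc(a), write_swc(c2)))
})

test_that("zero branching probability yields unbranched primaries", {
  p <- genotype_preset("flat", branch_prob_by_order = rep(0, 6))
  tr <- generate_arbor(p, seed = 2)
  bo <- branch_order_profile(tr)
  expect_equal(attr(bo, "max_order"), 1L)
  expect_equal(sum(bo$n_branch_points), 0L)
})

test_that("runaway presets are rejected up front", {
  p <- genotype_preset("boom", branch_prob_by_order = rep(1, 14))
  expect_error(generate_arbor(p, seed = 1), "runaway")
})

test_that("generated trees pass validation and the quality filter", {
  pres <- default_presets()
  for (g in names(pres)) {
    tr <- generate_arbor(pres[[g]], seed = 60 + match(g, names(pres)))
    reread <- read_swc(write_swc(tr))      # full parse-side validation
    expect_s3_class(reread, "neuron_tree")
    np <- length(tr$basal_roots)
    dec <- filter_reconstruction(list(
      genotype_determined = TRUE, n_primary_intact = np,
      n_primary_total = np, tips_visible = TRUE,
      apical_visible_length_um = 100))
    expect_true(dec$keep)
    expect_gte(np, 3L)
  }
})

test_that("tree populations match the branching-process expectation", {
  p <- default_presets()[["MeCP2+"]]
  exp_counts <- preset_expectations(p)
  s <- do.call(rbind, lapply(1:300, function(i)
    neuron_summary(generate_arbor(p, seed = 1e5 + i))))
  expect_equal(mean(s$n_branches), exp_counts$expected_branches,
               tolerance = 0.05)
  expect_equal(mean(s$n_branch_points),
               exp_counts$expected_branch_points, tolerance = 0.05)
  expect_equal(mean(s$total_length_um),
               exp_counts$expected_total_length_um, tolerance = 0.05)
})

test_that("default presets hit their calibration surface", {
  pres <- default_presets()
  sim <- function(g, n = 100, off = 0)
    do.call(rbind, lapply(seq_len(n), function(i)
      neuron_summary(generate_arbor(pres[[g]], seed = 2e5 + off + i))))
  sp <- sim("MeCP2+"); sm <- sim("MeCP2-", off = 5000)
  # population cumulative length near the 1873.9 um reference
  expect_equal(mean(sp$total_length_um), 1873.9, tolerance = 0.05)
  # branch-point deficit of the mutant-expressing genotype
  deficit <- mean(sp$n_branch_points) - mean(sm$n_branch_points)
  expect_gt(deficit, 1.8); expect_lt(deficit, 3.4)
  # unchanged primaries and per-branch geometry (null contrasts)
  expect_equal(mean(sp$n_primary), mean(sm$n_primary), tolerance = 0.06)
  expect_equal(mean(sp$mean_branch_length_um),
               mean(sm$mean_branch_length_um), tolerance = 0.05)
  expect_equal(mean(sp$mean_contraction), mean(sm$mean_contraction),
               tolerance = 0.02)
  expect_gt(mean(sp$mean_contraction), 0.85)
  expect_lt(mean(sp$mean_contraction), 0.93)
  # radial reach is only approximately preserved: with fewer high-order
  # branches the branching-process trees end somewhat shallower
  expect_equal(mean(sp$max_radial_distance_um),
               mean(sm$max_radial_distance_um), tolerance = 0.1)
})

test_that("mean branch length per order is genotype-independent", {
  pres <- default_presets()
  per_order <- function(g, off) {
    rows <- lapply(1:60, function(i)
      as.data.frame(branch_order_profile(
        generate_arbor(pres[[g]], seed = 3e5 + off + i))))
    d <- do.call(rbind, rows)
    tapply(d$mean_branch_length_um, d$order, mean, na.rm = TRUE)[1:4]
  }
  mp <- per_order("MeCP2+", 0); mm <- per_order("MeCP2-", 900)
  expect_equal(as.numeric(mp), as.numeric(mm), tolerance = 0.07)
})

test_that("cohorts are deterministic and respect the cell-count range", {
  spec <- cohort_spec(seed = 5, n_animals = 2, cells_per_animal = c(4, 6),
                      n_size_animals = 3, n_wt_size_animals = 1,
                      size_cells_per_animal = c(8, 10))
  a <- generate_cohort(default_presets(), spec)
  b <- generate_cohort(default_presets(), spec)
  expect_identical(a$reconstruction_metadata, b$reconstruction_metadata)
  expect_identical(a$outlines, b$outlines)
  expect_identical(write_swc(a$trees[[1]]), write_swc(b$trees[[1]]))
  counts <- table(a$reconstruction_metadata$animal_id)
  expect_true(all(counts >= 4 & counts <= 6))
  expect_equal(length(unique(a$reconstruction_metadata$genotype)), 3L)
  sc <- table(a$size_metadata$animal_id)
  expect_true(all(sc >= 8 & sc <= 10))
})

test_that("equal presets with no animal effect give unit size ratios", {
  pres <- default_presets()
  pres[["MeCP2-"]] <- pres[["MeCP2+"]]      # same size model
  pres[["MeCP2-"]]$name <- "MeCP2-"
  co <- generate_cohort(pres,
                        cohort_spec(seed = 9, n_size_animals = 6,
                                    n_wt_size_animals = 0,
                                    size_cells_per_animal = c(60, 80),
                                    animal_effect_sd = 0,
                                    xci_range = c(0.4, 0.6)),
                        include_arbors = FALSE)
  sizes <- cell_size_table(co$outlines, co$size_metadata)
  ratios <- vapply(split(sizes, sizes$animal_id), function(r)
    normalize_within_animal(r)$soma_ratio, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("the XCI-dependent size gradient is recoverable by regression", {
  slopes <- numeric(); ps <- numeric()
  for (sd0 in 1:5) {
    co <- generate_cohort(default_presets(),
                          cohort_spec(seed = sd0, n_wt_size_animals = 0),
                          include_arbors = FALSE)
    sizes <- cell_size_table(co$outlines, co$size_metadata)
    inc <- apply_inclusion(sizes)$included
    d <- do.call(rbind, lapply(split(inc, inc$animal_id), function(r)
      data.frame(xci = xci_fraction(r$genotype),
                 ratio = normalize_within_animal(r)$soma_ratio)))
    fit <- linear_regression(d$xci, d$ratio)
    slopes <- c(slopes, fit$slope); ps <- c(ps, fit$p)
  }
  expect_gte(sum(slopes > 0), 4L)          # positive sign recovered
  expect_gte(sum(ps < 0.05), 3L)           # significant at 24 animals
})

test_that("order 2-3 branch-point deficits keep their sign across cohorts", {
  pres <- default_presets()
  sign_ok <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    per_geno <- lapply(c("MeCP2+", "MeCP2-"), function(g) {
      rows <- lapply(1:100, function(i) {
        bo <- branch_order_profile(generate_arbor(
          pres[[g]], seed = 4e5 + r * 1000 + i + (g == "MeCP2-") * 500))
        c(o2 = if (nrow(bo) >= 2) bo$n_branch_points[2] else 0,
          o3 = if (nrow(bo) >= 3) bo$n_branch_points[3] else 0)
      })
      colMeans(do.call(rbind, rows))
    })
    d <- per_geno[[2]] - per_geno[[1]]
    sign_ok <- sign_ok + (d["o2"] < 0 && d["o3"] < 0)
  }
  expect_gte(sign_ok, n_rep - 1L)
})

test_that("the written cohort round-trips through the file formats", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(seed = 77, n_animals = 1, cells_per_animal = c(3, 3),
                      n_size_animals = 2, n_wt_size_animals = 0,
                      size_cells_per_animal = c(5, 6))
  co <- generate_cohort(default_presets(), spec)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.yml")))
  meta <- read.csv(file.path(dir, "reconstruction_metadata.csv"))
  expect_equal(nrow(meta), length(co$trees))
  tr <- read_swc(file.path(dir, "swc", paste0(meta$cell_id[1], ".swc")))
  expect_equal(tr$nodes, co$trees[[meta$cell_id[1]]]$nodes,
               tolerance = 1e-9)
})
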