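# run code under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-cell stream: hash of (seed, animal index, cell index),
# kept below 2^31 so it is a valid set.seed() argument everywhere
.cell_seed <- function(seed, animal, cell = 0L) {
  h <- (abs(as.numeric(seed)) %% 1e9) * 1009 +
    as.numeric(animal) * 10007 + as.numeric(cell) * 101 + 12345
  as.integer(h %% 2147483646) + 1L
}

# uniform integer in [a, b]; immune to sample()'s scalar expansion
.sample_range <- function(a, b) {
  if (a == b) return(as.integer(a))
  sample(seq.int(a, b), 1L)
}

.unit_sphere <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v * v))
}

.steer <- function(dir, kappa) {
  v <- kappa * dir + rnorm(3)
  v / sqrt(sum(v * v))
}

#' Generate one synthetic neuron reconstruction
#'
#' Grows a rooted SWC tree from a [genotype_preset()]: the number of
#' primary basal dendrites is drawn around `n_primary_mean`; an order-k
#' branch bifurcates with probability `branch_prob_by_order[k]`; branch
#' path lengths are gamma-distributed and paths are persistent 3D
#' random walks (persistence `tortuosity_kappa` within a branch,
#' `daughter_kappa` across branch points), which sets the contraction.
#' A straight 100-micrometre apical stub (type 4) is attached so
#' generated cells satisfy the apical-visibility quality criterion; it
#' is excluded from basal morphometry by construction.  Output is fully
#' reproducible from `(preset, seed)`.
#'
#' @param preset a [genotype_preset()].
#' @param seed integer seed for this cell's private RNG stream.
#' @inheritParams neuron_tree
#' @return A [neuron_tree()].
#' @export
generate_arbor <- function(preset, seed, cell_id = NA_character_,
                           animal_id = NA_character_,
                           genotype = preset$name) {
  exp_n <- preset_expectations(preset)$expected_branches
  if (exp_n > 1e4)
    stop("preset yields runaway trees (expected branches > 10000)")
  .with_seed(seed, {
    m <- preset$n_primary_mean
    n_primary <- max(1L, floor(m) + rbinom(1L, 1L, m - floor(m)) +
                       sample(c(-1L, 0L, 1L), 1L,
                              prob = c(0.25, 0.5, 0.25)))
    step <- preset$step_um
    p_ord <- preset$branch_prob_by_order
    ids <- list(); types <- list(); xs <- list(); ys <- list()
    zs <- list(); rads <- list(); parents <- list()
    next_id <- 1L
    add <- function(id, type, xyz, radius, parent) {
      k <- length(ids) + 1L
      ids[[k]] <<- id; types[[k]] <<- type
      xs[[k]] <<- xyz[, 1]; ys[[k]] <<- xyz[, 2]; zs[[k]] <<- xyz[, 3]
      rads[[k]] <<- radius; parents[[k]] <<- parent
    }
    add(1L, SWC_SOMA, matrix(0, 1, 3), 6, -1L)
    next_id <- 2L
    # stack of branches to grow: start position, direction, order, parent id
    stack <- lapply(seq_len(n_primary), function(i)
      list(pos = c(0, 0, 0), dir = .unit_sphere(), order = 1L,
           parent = 1L))
    while (length(stack)) {
      b <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      len <- rgamma(1L, shape = preset$branch_length_shape,
                    scale = preset$branch_length_scale)
      n_steps <- max(1L, as.integer(round(len / step)))
      pts <- matrix(0, n_steps, 3L)
      pos <- b$pos; dir <- b$dir
      for (s in seq_len(n_steps)) {
        pos <- pos + dir * step
        pts[s, ] <- pos
        dir <- .steer(dir, preset$tortuosity_kappa)
      }
      new_ids <- seq.int(next_id, next_id + n_steps - 1L)
      add(new_ids, rep(SWC_BASAL, n_steps), pts, rep(0.8, n_steps),
          c(b$parent, new_ids[-n_steps]))
      next_id <- next_id + n_steps
      p_k <- if (b$order <= length(p_ord)) p_ord[b$order] else 0
      if (runif(1L) < p_k) {
        for (j in 1:2)
          stack[[length(stack) + 1L]] <- list(
            pos = pos, dir = .steer(dir, preset$daughter_kappa),
            order = b$order + 1L, parent = new_ids[n_steps])
      }
    }
    # apical stub: straight, 10 nodes x 10 um
    ap <- cbind(0, 0, seq(10, 100, by = 10))
    ap_ids <- seq.int(next_id, next_id + 9L)
    add(ap_ids, rep(SWC_APICAL, 10L), ap, rep(1.5, 10L),
        c(1L, ap_ids[-10L]))
    nodes <- data.frame(id = unlist(ids), type = unlist(types),
                        x = round(unlist(xs), 4),
                        y = round(unlist(ys), 4),
                        z = round(unlist(zs), 4),
                        radius = unlist(rads), parent = unlist(parents))
    neuron_tree(nodes, cell_id = cell_id, animal_id = animal_id,
                genotype = genotype)
  })
}

# closed outline polygon with exact target area: noisy ellipse rescaled
.outline_polygon <- function(area, n_vertices = 24L) {
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  q <- runif(1L, 0.7, 0.95)
  theta <- runif(1L, 0, pi)
  r <- (1 + 0.06 * rnorm(n_vertices))
  x0 <- r * cos(phi); y0 <- q * r * sin(phi)
  x <- x0 * cos(theta) - y0 * sin(theta)
  y <- x0 * sin(theta) + y0 * cos(theta)
  a0 <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  s <- sqrt(area / a0)
  cbind(x = x * s, y = y * s)
}

#' Generate a full synthetic cohort
#'
#' Produces (a) an arbor cohort — per genotype, `n_animals` animals
#' with 16-31 reconstructed cells each, grown from the genotype's
#' preset, with clean reconstruction-quality metadata — and (b) a
#' mosaic cell-size cohort of heterozygous animals (plus wild-type
#' animals) with per-animal X-inactivation fractions, ages, severity
#' scores, a between-animal multiplicative size effect, and per-cell
#' soma/nucleus outlines whose areas follow the preset size model; the
#' MeCP2- / MeCP2+ size ratio varies with the animal's XCI fraction
#' through `xci_size_slope`.  Every cell uses a private RNG stream
#' hashed from `(seed, animal, cell)`, so changing cohort composition
#' does not cascade into other cells' draws.
#'
#' @param presets named list of three [genotype_preset()]s
#'   (`WT`, `MeCP2+`, `MeCP2-`), e.g. [default_presets()].
#' @param spec a [cohort_spec()].
#' @param include_arbors,include_sizes generate the reconstruction and
#'   the cell-size components (both default `TRUE`).
#' @return A list of class `cohort`: `trees` (named list of
#'   [neuron_tree()]), `reconstruction_metadata`, `outlines`,
#'   `size_metadata`, `animals`, plus the `presets` and `spec` used.
#' @export
generate_cohort <- function(presets, spec = cohort_spec(),
                            include_arbors = TRUE, include_sizes = TRUE) {
  stopifnot(all(c("WT", "MeCP2+", "MeCP2-") %in% names(presets)))
  seed <- spec$seed
  code_of <- c("WT" = "WT", "MeCP2+" = "PLUS", "MeCP2-" = "MINUS")
  trees <- list(); recon_meta <- list()
  animal_counter <- 0L
  if (include_arbors) {
    for (g in c("WT", "MeCP2+", "MeCP2-")) {
      for (a in seq_len(spec$n_animals)) {
        animal_counter <- animal_counter + 1L
        aid <- sprintf("arb_%s_%02d", code_of[[g]], a)
        n_cells <- .with_seed(.cell_seed(seed, animal_counter, 0L),
                              .sample_range(spec$cells_per_animal[1],
                                            spec$cells_per_animal[2]))
        for (cc in seq_len(n_cells)) {
          cid <- sprintf("%s_c%03d", aid, cc)
          tr <- generate_arbor(presets[[g]],
                               seed = .cell_seed(seed, animal_counter, cc),
                               cell_id = cid, animal_id = aid, genotype = g)
          trees[[cid]] <- tr
          np <- length(tr$basal_roots)
          recon_meta[[cid]] <- data.frame(
            cell_id = cid, animal_id = aid, genotype = g,
            genotype_determined = TRUE, n_primary_intact = np,
            n_primary_total = np, tips_visible = TRUE,
            apical_visible_length_um = 100)
        }
      }
    }
  }
  outlines <- list(); size_meta <- list(); animals <- list()
  if (include_sizes) {
    plus <- presets[["MeCP2+"]]; minus <- presets[["MeCP2-"]]
    wt <- presets[["WT"]]
    n_het <- spec$n_size_animals; n_wt <- spec$n_wt_size_animals
    for (a in seq_len(n_het + n_wt)) {
      animal_counter <- animal_counter + 1L
      is_het <- a <= n_het
      aid <- sprintf("size_%s_%02d", if (is_het) "HET" else "WT", a)
      adraw <- .with_seed(.cell_seed(seed, animal_counter, 0L), {
        list(xci = runif(1L, spec$xci_range[1], spec$xci_range[2]),
             age = runif(1L, spec$age_range_months[1],
                         spec$age_range_months[2]),
             effect = rlnorm(1L, -spec$animal_effect_sd^2 / 2,
                             spec$animal_effect_sd),
             n_cells = .sample_range(spec$size_cells_per_animal[1],
                                     spec$size_cells_per_animal[2]),
             items = list(tremor = sample(0:2, 1L),
                          hind_clasp = sample(0:3, 1L),
                          fur = sample(0:2, 1L),
                          activity = sample(0:3, 1L),
                          breathing = sample(0:2, 1L),
                          hunched = sample(0:2, 1L)))
      })
      xci <- if (is_het) adraw$xci else NA_real_
      ratio_s <- if (is_het)
        minus$soma_area_mean / plus$soma_area_mean +
          minus$xci_size_slope * (xci - minus$xci_ref) else NA_real_
      ratio_n <- if (is_het)
        minus$nucleus_area_mean / plus$nucleus_area_mean +
          minus$xci_size_slope * (xci - minus$xci_ref) else NA_real_
      animals[[aid]] <- data.frame(
        animal_id = aid, group = if (is_het) "het" else "wt",
        xci_fraction_minus = xci, age_months = adraw$age,
        tremor = adraw$items$tremor, hind_clasp = adraw$items$hind_clasp,
        fur = adraw$items$fur, activity = adraw$items$activity,
        breathing = adraw$items$breathing, hunched = adraw$items$hunched,
        phenotype_score = phenotype_score(adraw$items))
      for (cc in seq_len(adraw$n_cells)) {
        cid <- sprintf("%s_c%03d", aid, cc)
        cell <- .with_seed(.cell_seed(seed, animal_counter, cc), {
          if (is_het) {
            g <- if (runif(1L) < xci) "MeCP2-" else "MeCP2+"
            s_mean <- plus$soma_area_mean * adraw$effect *
              (if (g == "MeCP2-") ratio_s else 1)
            n_mean <- plus$nucleus_area_mean * adraw$effect *
              (if (g == "MeCP2-") ratio_n else 1)
          } else {
            g <- "WT"
            s_mean <- wt$soma_area_mean * adraw$effect
            n_mean <- wt$nucleus_area_mean * adraw$effect
          }
          cv <- plus$soma_area_cv
          sdlog <- sqrt(log(1 + cv^2))
          soma <- rlnorm(1L, log(s_mean) - sdlog^2 / 2, sdlog)
          nucl <- max(0.3 * n_mean,
                      (n_mean / s_mean) * soma +
                        rnorm(1L, 0, n_mean * plus$nucleus_area_cv))
          list(genotype = g, soma = soma, nucleus = nucl,
               soma_poly = .outline_polygon(soma),
               nucleus_poly = .outline_polygon(nucl),
               slice = sample(1:3, 1L),
               focus = runif(1L) > 0.03,
               unoccluded = runif(1L) > 0.03,
               identifiable = runif(1L) > 0.02)
        })
        size_meta[[cid]] <- data.frame(
          cell_id = cid, animal_id = aid, genotype = cell$genotype,
          slice_id = cell$slice,
          nucleus_in_focus = cell$focus,
          soma_unoccluded = cell$unoccluded,
          genotype_identifiable = cell$identifiable)
        nv <- nrow(cell$soma_poly)
        outlines[[cid]] <- data.frame(
          cell_id = cid,
          structure = rep(c("soma", "nucleus"), each = nv),
          vertex_index = rep(seq_len(nv), 2L),
          x_um = round(c(cell$soma_poly[, 1], cell$nucleus_poly[, 1]), 4),
          y_um = round(c(cell$soma_poly[, 2], cell$nucleus_poly[, 2]), 4))
      }
    }
  }
  structure(list(
    trees = trees,
    reconstruction_metadata = if (length(recon_meta))
      do.call(rbind, c(recon_meta, make.row.names = FALSE)) else NULL,
    outlines = if (length(outlines))
      do.call(rbind, c(outlines, make.row.names = FALSE)) else NULL,
    size_metadata = if (length(size_meta))
      do.call(rbind, c(size_meta, make.row.names = FALSE)) else NULL,
    animals = if (length(animals))
      do.call(rbind, c(animals, make.row.names = FALSE)) else NULL,
    presets = presets, spec = spec), class = "cohort")
}

#' Write a generated cohort to disk
#'
#' Emits the exact dialects the analysis side consumes: one SWC file
#' per reconstructed cell under `swc/`, CSV tables
#' (`reconstruction_metadata.csv`, `outlines.csv`, `size_metadata.csv`,
#' `animals.csv`) and a YAML manifest recording presets, cohort
#' specification and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "swc"), recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$trees)
    write_swc(tr, file.path(dir, "swc", paste0(tr$cell_id, ".swc")))
  wr <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(cohort$reconstruction_metadata, "reconstruction_metadata.csv")
  wr(cohort$outlines, "outlines.csv")
  wr(cohort$size_metadata, "size_metadata.csv")
  wr(cohort$animals, "animals.csv")
  manifest <- list(
    seed = cohort$spec$seed,
    spec = unclass(cohort$spec),
    presets = lapply(cohort$presets, unclass))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}
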