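#' Reference population means for calibration
#'
#' Per-genotype population means of the basal-arbor and cell-size
#' parameters of layer V pyramidal neurons in the mosaic heterozygous
#' Rett-model mouse cortex (genotypes: cells from wild-type brains
#' `WT`, and wild-type-expressing `MeCP2+` / mutant-expressing `MeCP2-`
#' cells in heterozygous brains).  These values are the calibration
#' surface for [default_presets()] and the inputs to the worked-example
#' genotype contrasts (percent reductions are ratios of these means).
#'
#' @return A data.frame with one row per parameter and one column per
#'   genotype.
#' @export
reference_means <- function() {
  out <- data.frame(
    parameter = c("cumulative_length_um", "total_branch_points",
                  "second_order_branch_points", "third_order_branch_points",
                  "third_order_branches", "fourth_order_branches",
                  "third_order_length_um", "fourth_order_length_um",
                  "max_radial_distance_um",
                  "soma_area_um2", "nucleus_area_um2"),
    WT = c(1898.5, 16.5, 5.3, 3.7, 11.0, 7.0, 599.5, 414.0, 159.7,
           184.6, 117.9),
    `MeCP2+` = c(1873.9, 16.2, 5.1, 3.2, 10.6, 6.2, 554.6, 380.2, 155.5,
                 169.2, 107.9),
    `MeCP2-` = c(1600.6, 13.7, 4.6, 2.7, 9.2, 5.3, 499.8, 300.3, 149.7,
                 143.3, 93.3),
    check.names = FALSE)
  rownames(out) <- out$parameter
  out
}

#' Construct a genotype preset for the arbor/size generator
#'
#' A preset fixes the generative parameters for one neuronal genotype:
#' the branching process (expected primary dendrites and the per-order
#' probability that a branch of centrifugal order k bifurcates), the
#' branch length distribution (gamma), path tortuosity (directional
#' persistence of the 3D random walk), and the soma/nucleus size model
#' (log-normal soma areas; nucleus conditionally linear in soma).
#' `xci_size_slope` is the change in the MeCP2-/MeCP2+ size ratio per
#' unit X-inactivation fraction, centred at `xci_ref`.
#'
#' @param name genotype label.
#' @param n_primary_mean expected number of primary basal dendrites.
#' @param branch_prob_by_order numeric vector; element k is the
#'   probability that an order-k branch ends in a bifurcation (orders
#'   beyond the vector do not branch).
#' @param branch_length_shape,branch_length_scale gamma parameters of
#'   branch path length (micrometres).
#' @param tortuosity_kappa directional persistence of the within-branch
#'   random walk (larger = straighter; calibrated so mean contraction
#'   is about 0.9).
#' @param daughter_kappa directional persistence across a branch point
#'   (smaller = wider daughter spread).
#' @param step_um path sampling step (micrometres).
#' @param soma_area_mean,soma_area_cv log-normal soma area mean and
#'   coefficient of variation (square micrometres; dimensionless).
#' @param nucleus_area_mean mean nucleus area (square micrometres).
#' @param nucleus_area_cv residual CV of nucleus area around its
#'   soma-conditional mean.
#' @param xci_size_slope per-unit-XCI change in the MeCP2- size ratio.
#' @param xci_ref XCI fraction at which the preset size means apply.
#' @return A list of class `genotype_preset`.
#' @export
genotype_preset <- function(name,
                            n_primary_mean = 5,
                            branch_prob_by_order,
                            branch_length_shape = 3,
                            branch_length_scale = 16.7,
                            tortuosity_kappa = 3.6,
                            daughter_kappa = 0.2,
                            step_um = 5,
                            soma_area_mean = 169.2,
                            soma_area_cv = 0.15,
                            nucleus_area_mean = 107.9,
                            nucleus_area_cv = 0.08,
                            xci_size_slope = 0,
                            xci_ref = 0.34) {
  stopifnot(n_primary_mean >= 1,
            all(branch_prob_by_order >= 0 & branch_prob_by_order <= 1),
            branch_length_shape > 0, branch_length_scale > 0,
            tortuosity_kappa > 0, step_um > 0,
            soma_area_mean > 0, soma_area_cv > 0,
            nucleus_area_mean > 0, nucleus_area_cv > 0)
  structure(list(name = name, n_primary_mean = n_primary_mean,
                 branch_prob_by_order = branch_prob_by_order,
                 branch_length_shape = branch_length_shape,
                 branch_length_scale = branch_length_scale,
                 tortuosity_kappa = tortuosity_kappa,
                 daughter_kappa = daughter_kappa,
                 step_um = step_um,
                 soma_area_mean = soma_area_mean,
                 soma_area_cv = soma_area_cv,
                 nucleus_area_mean = nucleus_area_mean,
                 nucleus_area_cv = nucleus_area_cv,
                 xci_size_slope = xci_size_slope,
                 xci_ref = xci_ref),
            class = "genotype_preset")
}

#' Expected branch and branch-point counts of a preset
#'
#' Closed-form expectations of the order-indexed branching process:
#' with `n_1` expected primaries and continuation probabilities `p_k`,
#' the expected number of order-k branches is
#' `n_k = n_1 * prod_{j<k} 2 p_j` and the expected branch-point total is
#' `sum_k n_k p_k`.
#'
#' @param preset a [genotype_preset()].
#' @return A list with `n_branches_by_order`, `expected_branches`,
#'   `expected_branch_points`, `expected_total_length_um`.
#' @export
preset_expectations <- function(preset) {
  p <- preset$branch_prob_by_order
  n_k <- numeric(length(p) + 1L)
  n_k[1L] <- preset$n_primary_mean
  for (k in seq_along(p)) n_k[k + 1L] <- 2 * n_k[k] * p[k]
  bp <- sum(n_k[seq_along(p)] * p)
  branches <- sum(n_k)
  mean_len <- preset$branch_length_shape * preset$branch_length_scale
  list(n_branches_by_order = n_k,
       expected_branches = branches,
       expected_branch_points = bp,
       expected_total_length_um = branches * mean_len)
}

#' Calibrated default genotype presets
#'
#' Three presets whose population means approximate the reference
#' genotype means of [reference_means()]: `WT` and `MeCP2+` share
#' identical arbor parameters (expected cumulative length about 1874
#' micrometres, about 16 branch points); the `MeCP2-` preset lowers the
#' bifurcation probability at orders 2-3, the region where the deficit
#' is localised, giving about 14 branch points and about 1630
#' micrometres with unchanged primaries, mean branch length,
#' tortuosity and radial reach.  Size models: log-normal areas with the
#' reference means; `WT` somata/nuclei larger than `MeCP2+`; the
#' `MeCP2-` ratio to `MeCP2+` increases with the animal's MeCP2-
#' fraction (slope 0.25/unit XCI), so highly skewed-toward-wild-type
#' animals show the largest deficit.
#'
#' @return Named list of three [genotype_preset()] objects
#'   (`WT`, `MeCP2+`, `MeCP2-`).
#' @export
default_presets <- function() {
  # order-k bifurcation probabilities chosen so the branching-process
  # expectations hit the reference branch-point pattern
  p_plus <- c(0.96, 0.531, 0.314, 0.297, 0.237, 0.167)
  p_minus <- c(0.96, 0.453, 0.270, 0.297, 0.237, 0.167)
  ref <- reference_means()
  list(
    "WT" = genotype_preset(
      "WT", branch_prob_by_order = p_plus,
      soma_area_mean = ref["soma_area_um2", "WT"],
      nucleus_area_mean = ref["nucleus_area_um2", "WT"]),
    "MeCP2+" = genotype_preset(
      "MeCP2+", branch_prob_by_order = p_plus,
      soma_area_mean = ref["soma_area_um2", "MeCP2+"],
      nucleus_area_mean = ref["nucleus_area_um2", "MeCP2+"]),
    "MeCP2-" = genotype_preset(
      "MeCP2-", branch_prob_by_order = p_minus,
      soma_area_mean = ref["soma_area_um2", "MeCP2-"],
      nucleus_area_mean = ref["nucleus_area_um2", "MeCP2-"],
      xci_size_slope = 0.25))
}

#' Cohort specification for the generator
#'
#' @param n_animals animals per genotype in the arbor cohort.
#' @param cells_per_animal inclusive range of reconstructed cells per
#'   animal.
#' @param n_size_animals heterozygous animals in the cell-size cohort.
#' @param n_wt_size_animals wild-type animals in the cell-size cohort.
#' @param size_cells_per_animal inclusive range of measured cells per
#'   size-cohort animal.
#' @param xci_range range of per-animal MeCP2- fractions.
#' @param age_range_months range of animal ages.
#' @param animal_effect_sd between-animal multiplicative (log-normal)
#'   size variation.
#' @param seed master seed; every cell stream is derived from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 5, cells_per_animal = c(16, 31),
                        n_size_animals = 24, n_wt_size_animals = 10,
                        size_cells_per_animal = c(30, 80),
                        xci_range = c(0.12, 0.56),
                        age_range_months = c(5, 21),
                        animal_effect_sd = 0.12,
                        seed = 1L) {
  stopifnot(n_animals >= 1, all(cells_per_animal >= 1),
            all(xci_range >= 0 & xci_range <= 1),
            animal_effect_sd >= 0)
  structure(list(n_animals = n_animals,
                 cells_per_animal = cells_per_animal,
                 n_size_animals = n_size_animals,
                 n_wt_size_animals = n_wt_size_animals,
                 size_cells_per_animal = size_cells_per_animal,
                 xci_range = xci_range,
                 age_range_months = age_range_months,
                 animal_effect_sd = animal_effect_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}
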