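#' @importFrom stats aggregate anova aov coef complete.cases lm pf
#'   predict pt resid rgamma rlnorm rnorm rpois runif sd setNames var
#'   wilcox.test quantile
#' @importFrom utils read.csv write.csv
NULL

# SWC type codes used throughout (standard convention)
SWC_SOMA   <- 1L
SWC_BASAL  <- 3L
SWC_APICAL <- 4L

swc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mosaicmorph_error")))
}

#' Construct a neuron tree from an SWC node table
#'
#' A `neuron_tree` is a rooted tree of SWC nodes with a defined soma
#' origin.  The soma centroid (origin for all radial distances) is the
#' unweighted mean of the coordinates of all soma (type 1) nodes, so
#' single-node, multi-node and three-point-cylinder soma dialects are all
#' accepted.  Primary basal dendrites are type-3 nodes whose parent is a
#' soma node; their subtrees feed all basal morphometry.  Apical (type 4)
#' subtrees are retained but excluded from basal analyses.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (coordinates and radius in micrometres; `parent`
#'   is `-1` for the root).  Parents must be declared before children.
#' @param cell_id,animal_id,genotype optional labels carried through the
#'   pipeline.
#' @return An object of class `neuron_tree`: a list with elements
#'   `nodes`, `soma_centroid`, `basal_roots`, `apical_roots`, `cell_id`,
#'   `animal_id`, `genotype`.
#' @export
neuron_tree <- function(nodes, cell_id = NA_character_,
                        animal_id = NA_character_,
                        genotype = NA_character_) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes)))
    swc_error("node table must have columns id, type, x, y, z, radius, parent",
              "swc_format_error")
  nodes <- as.data.frame(nodes)[required]
  if (nrow(nodes) == 0L)
    swc_error("node table is empty", "swc_format_error")
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  if (anyNA(nodes))
    swc_error("node table contains missing or non-numeric values",
              "swc_format_error")
  if (any(nodes$id <= 0L))
    swc_error("node ids must be positive integers", "swc_format_error")
  if (anyDuplicated(nodes$id))
    swc_error(sprintf("duplicate node id: %d",
                      nodes$id[anyDuplicated(nodes$id)]),
              "swc_format_error")
  if (any(nodes$radius < 0))
    swc_error("negative radius", "swc_format_error")

  root <- which(nodes$parent == -1L)
  if (length(root) == 0L)
    swc_error("no root node (parent -1)", "swc_structure_error")
  if (length(root) > 1L)
    swc_error("more than one root node", "swc_structure_error")

  # every non-root parent must refer to an earlier-declared node; this
  # single ordering rule also rules out cycles and disconnection
  nonroot <- nodes$parent != -1L
  pos <- match(nodes$parent[nonroot], nodes$id)
  if (anyNA(pos)) {
    bad <- nodes$id[nonroot][is.na(pos)][1L]
    swc_error(sprintf("node %d references a missing parent", bad),
              "swc_structure_error")
  }
  if (any(pos >= which(nonroot))) {
    bad <- nodes$id[nonroot][pos >= which(nonroot)][1L]
    swc_error(sprintf("node %d references a parent declared later", bad),
              "swc_structure_error")
  }

  soma <- nodes$type == SWC_SOMA
  if (!any(soma))
    swc_error("no soma (type 1) node; soma origin undefined",
              "swc_structure_error")
  centroid <- c(mean(nodes$x[soma]), mean(nodes$y[soma]), mean(nodes$z[soma]))

  parent_type <- nodes$type[match(nodes$parent, nodes$id)]
  basal_roots <- nodes$id[nodes$type == SWC_BASAL &
                            !is.na(parent_type) & parent_type == SWC_SOMA]
  apical_roots <- nodes$id[nodes$type == SWC_APICAL &
                             !is.na(parent_type) & parent_type == SWC_SOMA]

  structure(list(nodes = nodes,
                 soma_centroid = centroid,
                 basal_roots = basal_roots,
                 apical_roots = apical_roots,
                 cell_id = cell_id,
                 animal_id = animal_id,
                 genotype = genotype),
            class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf(
    "<neuron_tree> %s: %d nodes, %d basal root(s), %d apical root(s)\n",
    ifelse(is.na(x$cell_id), "(unlabelled)", x$cell_id),
    nrow(x$nodes), length(x$basal_roots), length(x$apical_roots)))
  cat(sprintf("  soma centroid: (%.2f, %.2f, %.2f) um\n",
              x$soma_centroid[1], x$soma_centroid[2], x$soma_centroid[3]))
  invisible(x)
}

#' Read an SWC reconstruction
#'
#' Parses the standard seven-column whitespace-delimited SWC format
#' (`id type x y z radius parent`, `#` comment lines) into a validated
#' [neuron_tree()].  Coordinates are taken to be micrometres in a
#' right-handed frame; no axis flips are applied.
#'
#' @param file path to an SWC file, or a character vector of lines.
#' @inheritParams neuron_tree
#' @return A `neuron_tree`.
#' @export
read_swc <- function(file, cell_id = NA_character_,
                     animal_id = NA_character_, genotype = NA_character_) {
  lines <- if (length(file) == 1L && !grepl("\n", file) &&
               file.exists(file)) readLines(file) else
    unlist(strsplit(file, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    swc_error("no data lines in SWC input", "swc_format_error")
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    swc_error(sprintf("line %d does not have 7 columns",
                      which(nf != 7L)[1L]),
              "swc_format_error")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m))
    swc_error("non-numeric field in SWC input", "swc_format_error")
  nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7])
  neuron_tree(nodes, cell_id = cell_id, animal_id = animal_id,
              genotype = genotype)
}

#' Write a neuron tree as SWC
#'
#' Emits standard seven-column SWC, one node per line in stored order
#' (parents before children), coordinates and radii fixed to four decimal
#' places so output is byte-reproducible across platforms.
#'
#' @param tree a [neuron_tree()].
#' @param file path to write, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_swc <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "neuron_tree"))
  n <- tree$nodes
  if (nrow(n) == 0L)
    swc_error("cannot write a tree with no nodes", "swc_format_error")
  lines <- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                   n$id, n$type, n$x, n$y, n$z, n$radius, n$parent)
  header <- c("# SWC export (mosaicmorph)",
              "# id type x y z radius parent")
  out <- c(header, lines)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Reconstruction quality filter
#'
#' Applies the five inclusion criteria used when reconstructions come
#' from dye fills in acute slices: the decision rejects a cell when (1)
#' its genotype could not be determined, (2) fewer than three primary
#' dendrites are intact, (3) more than half of the primary dendrites were
#' chopped by slicing, (4) dendrite tips are not visible, or (5) no
#' apical dendrite of at least 75 micrometres is visible.  The apical
#' criterion is evaluated from the metadata flag, not recomputed from the
#' (possibly truncated) reconstruction, because it refers to visibility
#' in the slice.  The returned reason is the first failing criterion in
#' this order.
#'
#' @param flags a list or one-row data.frame with fields
#'   `genotype_determined`, `n_primary_intact`, `n_primary_total`,
#'   `tips_visible`, `apical_visible_length_um`.
#' @param tree optionally, the corresponding [neuron_tree()] (unused by
#'   the decision itself; accepted so callers can keep tree and flags
#'   together).
#' @param apical_min_um visibility threshold for the apical dendrite
#'   (micrometres; default 75).
#' @return A list with `keep` (logical) and `reason` (`NA` when kept,
#'   otherwise one of `"genotype_undetermined"`,
#'   `"fewer_than_three_primary"`, `"more_than_half_primary_chopped"`,
#'   `"tips_not_visible"`, `"apical_below_75um"`).
#' @export
filter_reconstruction <- function(flags, tree = NULL, apical_min_um = 75) {
  f <- as.list(flags)
  need <- c("genotype_determined", "n_primary_intact", "n_primary_total",
            "tips_visible", "apical_visible_length_um")
  if (!all(need %in% names(f)))
    stop("flags must contain: ", paste(need, collapse = ", "))
  if (f$n_primary_intact < 0 || f$n_primary_intact > f$n_primary_total)
    stop("require 0 <= n_primary_intact <= n_primary_total")
  reason <- if (!isTRUE(as.logical(f$genotype_determined)))
    "genotype_undetermined"
  else if (f$n_primary_intact < 3)
    "fewer_than_three_primary"
  else if ((f$n_primary_total - f$n_primary_intact) > f$n_primary_total / 2)
    "more_than_half_primary_chopped"
  else if (!isTRUE(as.logical(f$tips_visible)))
    "tips_not_visible"
  else if (f$apical_visible_length_um < apical_min_um)
    "apical_below_75um"
  else NA_character_
  list(keep = is.na(reason), reason = reason)
}

#' Apply the reconstruction filter to a metadata table
#'
#' @param metadata data.frame with one row per cell and the flag columns
#'   of [filter_reconstruction()] (plus any identifier columns, which are
#'   carried through).
#' @inheritParams filter_reconstruction
#' @return The input with logical `keep` and character `reason` columns
#'   appended.
#' @export
filter_reconstructions <- function(metadata, apical_min_um = 75) {
  dec <- lapply(seq_len(nrow(metadata)), function(i)
    filter_reconstruction(metadata[i, , drop = FALSE],
                          apical_min_um = apical_min_um))
  metadata$keep <- vapply(dec, `[[`, logical(1), "keep")
  metadata$reason <- vapply(dec, `[[`, character(1), "reason")
  metadata
}
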