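#' Area of a traced outline
#'
#' Absolute shoelace area of an implicitly closed polygon, as used for
#' manually traced soma (Nissl counterstain) and nucleus (DAPI)
#' outlines.  Self-intersecting outlines are rejected: a figure-eight
#' trace is a digitisation error, not a cell.
#'
#' @param outline two-column matrix or data.frame of vertices (x, y in
#'   micrometres), in drawing order; the polygon is closed implicitly.
#' @param check_simple verify that the outline is a simple polygon
#'   (default `TRUE`; O(n^2) segment test, fine at tracing resolution).
#' @return Area in square micrometres.
#' @export
polygon_area <- function(outline, check_simple = TRUE) {
  p <- as.matrix(outline)
  if (nrow(p) < 3L) stop("an outline needs at least 3 points")
  if (ncol(p) != 2L) stop("outline must have two columns (x, y)")
  if (check_simple && .self_intersects(p))
    stop("outline is self-intersecting")
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# proper-crossing test between all non-adjacent edge pairs
.self_intersects <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]      # skip edges sharing a vertex
    if (!length(js)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Build a cell-size table from outline and metadata tables
#'
#' Computes soma and nucleus areas from traced outlines.  Outline
#' coordinates are multiplied by `pixel_size_um` before area
#' computation, so tables digitised in pixels can be converted with an
#' explicit calibration factor (default 1: coordinates already in
#' micrometres).  A nucleus larger than its soma is biologically
#' implausible and is logged with a warning but not rejected.
#'
#' @param outlines data.frame with columns `cell_id`, `structure`
#'   (`"soma"` or `"nucleus"`), `vertex_index`, `x_um`, `y_um`.
#' @param metadata data.frame with one row per cell: `cell_id`,
#'   `animal_id`, `genotype` (`"WT"`, `"MeCP2+"` or `"MeCP2-"`), and
#'   logical flags `nucleus_in_focus`, `soma_unoccluded`,
#'   `genotype_identifiable`.
#' @param pixel_size_um micrometres per coordinate unit.
#' @return `metadata` with `soma_area_um2` and `nucleus_area_um2`
#'   columns appended.
#' @export
cell_size_table <- function(outlines, metadata, pixel_size_um = 1) {
  stopifnot(pixel_size_um > 0)
  area_of <- function(cid, what) {
    o <- outlines[outlines$cell_id == cid & outlines$structure == what, ]
    if (nrow(o) == 0L) return(NA_real_)
    o <- o[order(o$vertex_index), ]
    polygon_area(cbind(o$x_um, o$y_um) * pixel_size_um)
  }
  metadata$soma_area_um2 <- vapply(metadata$cell_id, area_of, numeric(1),
                                   what = "soma")
  metadata$nucleus_area_um2 <- vapply(metadata$cell_id, area_of, numeric(1),
                                      what = "nucleus")
  odd <- which(!is.na(metadata$nucleus_area_um2) &
                 !is.na(metadata$soma_area_um2) &
                 metadata$nucleus_area_um2 >= metadata$soma_area_um2)
  if (length(odd))
    warning(sprintf("%d cell(s) with nucleus area >= soma area: %s",
                    length(odd),
                    paste(metadata$cell_id[odd], collapse = ", ")))
  metadata
}

#' Apply the cell-size inclusion criteria
#'
#' A measured cell is kept only when its DAPI-stained nucleus is in
#' sharp focus, its soma is not occluded by overlying cells, and its
#' genotype is clearly identifiable from the antibody staining.
#'
#' @param records data.frame with logical columns `nucleus_in_focus`,
#'   `soma_unoccluded`, `genotype_identifiable`.
#' @return A list with `included` (the kept rows), `excluded` (the
#'   dropped rows with a `reason` column naming the first failing flag)
#'   and `rejection_counts` (named integer vector per reason).
#' @export
apply_inclusion <- function(records) {
  flags <- c("nucleus_in_focus", "soma_unoccluded", "genotype_identifiable")
  stopifnot(all(flags %in% names(records)))
  reason <- rep(NA_character_, nrow(records))
  for (f in rev(flags)) reason[!records[[f]]] <- f
  included <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  counts <- vapply(flags, function(f) sum(excluded$reason == f), integer(1))
  list(included = included, excluded = excluded, rejection_counts = counts)
}

#' X-inactivation ratio of one animal
#'
#' Fraction of genotyped cells in a heterozygous animal that express the
#' mutant allele (MeCP2-).  Cells labelled `"WT"` come from wild-type
#' animals and are excluded by definition.
#'
#' @param genotypes character vector of per-cell genotype calls.
#' @return Fraction in \[0, 1\], or `NA` (with a warning) when the
#'   animal has no genotyped heterozygote cells.
#' @export
xci_fraction <- function(genotypes) {
  minus <- sum(genotypes == "MeCP2-")
  plus <- sum(genotypes == "MeCP2+")
  if (minus + plus == 0L) {
    warning("no genotyped heterozygote cells; XCI fraction undefined")
    return(NA_real_)
  }
  minus / (minus + plus)
}

#' Within-animal genotype size normalisation
#'
#' Ratio of the mean MeCP2- area to the mean MeCP2+ area within one
#' animal (optionally within one slice), for soma and nucleus
#' separately.  Normalising within animal removes between-animal
#' differences in tissue preparation and fixation before the ratios are
#' compared across X-inactivation ratios.
#'
#' @param records data.frame for one animal with columns `genotype`,
#'   `soma_area_um2`, `nucleus_area_um2` (and `slice_id` if
#'   `by = "slice"`).
#' @param by `"animal"` (default: pool the animal's slices) or
#'   `"slice"` (one ratio per slice, then averaged).
#' @return A list with `soma_ratio` and `nucleus_ratio`; `NA` with a
#'   warning when either genotype is absent.
#' @export
normalize_within_animal <- function(records, by = c("animal", "slice")) {
  by <- match.arg(by)
  ratio1 <- function(r) {
    plus <- r$genotype == "MeCP2+"
    minus <- r$genotype == "MeCP2-"
    if (!any(plus) || !any(minus)) return(c(NA_real_, NA_real_))
    c(mean(r$soma_area_um2[minus]) / mean(r$soma_area_um2[plus]),
      mean(r$nucleus_area_um2[minus]) / mean(r$nucleus_area_um2[plus]))
  }
  if (by == "animal") {
    v <- ratio1(records)
  } else {
    per <- vapply(split(records, records$slice_id), ratio1, numeric(2))
    v <- rowMeans(per, na.rm = TRUE)
  }
  if (anyNA(v)) warning("a genotype is absent; normalised ratio undefined")
  list(soma_ratio = v[1], nucleus_ratio = v[2])
}

# severity item ranges (tremor, clasping, fur, activity, breathing, posture)
SEVERITY_MAXIMA <- c(tremor = 2L, hind_clasp = 3L, fur = 2L,
                     activity = 3L, breathing = 2L, hunched = 2L)

#' Phenotype severity score
#'
#' Sum of six observational item scores (tremor 0-2, hind-limb clasping
#' 0-3, fur condition 0-2, activity 0-3, breathing 0-2, hunched posture
#' 0-2), giving a total of 0-14.
#'
#' @param items named list or vector with entries `tremor`,
#'   `hind_clasp`, `fur`, `activity`, `breathing`, `hunched`.
#' @return Integer score 0-14.
#' @export
phenotype_score <- function(items) {
  items <- unlist(items)
  if (!all(names(SEVERITY_MAXIMA) %in% names(items)))
    stop("items must contain: ",
         paste(names(SEVERITY_MAXIMA), collapse = ", "))
  items <- items[names(SEVERITY_MAXIMA)]
  if (any(items < 0L) || any(items > SEVERITY_MAXIMA) ||
      any(items != round(items)))
    stop("severity item out of range")
  as.integer(sum(items))
}
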