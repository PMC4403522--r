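#' Partition asymmetry of a bifurcation
#'
#' `|T1 - T2| / (T1 + T2 - 2)` over the tip counts of the two daughter
#' trees.  Values of 1 and 0 indicate maximally asymmetric and symmetric
#' partitioning.  The (1, 1) case — both daughters single tips — is 0/0
#' in the formula and is defined here as 0, since such a split is
#' maximally symmetric.
#'
#' @param t1,t2 tip counts of the two daughter trees (positive integers,
#'   vectorised).
#' @return Numeric in \[0, 1\].
#' @export
partition_asymmetry <- function(t1, t2) {
  if (any(t1 < 1) || any(t2 < 1))
    stop("tip counts must be >= 1")
  ifelse(t1 + t2 == 2, 0, abs(t1 - t2) / (t1 + t2 - 2))
}

#' Branch contraction (straightness)
#'
#' Ratio of the Euclidean distance between a branch's endpoints to its
#' along-path length.  1 means perfectly straight; lower values mean more
#' tortuous branches.
#'
#' @param path matrix of branch sample points (rows ordered along the
#'   branch, columns x, y, z in micrometres), with at least two rows.
#' @return Numeric in (0, 1\].
#' @export
branch_contraction <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("a branch needs at least two points")
  d <- diff(path)
  path_length <- sum(sqrt(rowSums(d^2)))
  if (path_length == 0)
    stop("degenerate branch: zero path length")
  euclid <- sqrt(sum((path[nrow(path), ] - path[1L, ])^2))
  euclid / path_length
}

# children / tip-count bookkeeping shared by the branch walkers.
# Relies on the neuron_tree guarantee that parents precede children.
.tree_index <- function(tree) {
  n <- tree$nodes
  nn <- nrow(n)
  ppos <- match(n$parent, n$id)            # NA for root
  child_count <- tabulate(ppos[!is.na(ppos)], nbins = nn)
  children <- vector("list", nn)
  has_kids <- which(child_count > 0L)
  kid_rows <- which(!is.na(ppos))
  children[has_kids] <- split(kid_rows, ppos[kid_rows])[as.character(has_kids)]
  # tip counts per subtree: reverse declaration order is a post-order
  tips <- ifelse(child_count == 0L, 1L, 0L)
  for (i in rev(seq_len(nn))) {
    p <- ppos[i]
    if (!is.na(p)) tips[p] <- tips[p] + tips[i]
  }
  list(ppos = ppos, children = children, child_count = child_count,
       tips = tips)
}

#' Decompose the basal arbor into branches and branch points
#'
#' A branch is a length of dendrite between the soma and a branch point,
#' between two branch points, or between a branch point and a tip.
#' Orders are assigned centrifugally: primary dendrites (originating at
#' the soma) carry order 1 and the order increments at every node with
#' two or more daughters (multifurcations also increment by exactly 1).
#' Each bifurcation yields a branch-point record with the tip counts of
#' its two daughter trees and the resulting partition asymmetry;
#' multifurcations are recorded but excluded from asymmetry summaries.
#'
#' Only basal (type 3) subtrees are analysed; the short segment joining
#' the soma attachment node to the first basal sample is counted as part
#' of the primary branch, so branch path lengths, per-order totals and
#' Sholl shell totals all conserve the same cable.
#'
#' @param tree a [neuron_tree()].
#' @return A list of class `branch_set` with data.frames:
#'   * `branches`: one row per branch — `branch_id`, `order`,
#'     `start_id`, `end_id`, `n_nodes`, `path_length_um`,
#'     `euclidean_length_um`, `contraction`, `is_terminal`;
#'   * `branch_points`: one row per branch point — `node_id`, `x`, `y`,
#'     `z`, `order`, `n_daughters`, `t1`, `t2`, `partition_asymmetry`
#'     (`NA` at multifurcations), `radial_distance_um`;
#'   * `segments`: one row per basal compartment (`parent -> node`) —
#'     endpoint coordinates, `length_um`, `order`, `branch_id`.
#' @export
extract_branches <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  n <- tree$nodes
  idx <- .tree_index(tree)
  if (length(tree$basal_roots) == 0L) {
    warning("tree has no basal root; empty branch set")
    empty <- list(
      branches = data.frame(branch_id = integer(), order = integer(),
                            start_id = integer(), end_id = integer(),
                            n_nodes = integer(), path_length_um = numeric(),
                            euclidean_length_um = numeric(),
                            contraction = numeric(), is_terminal = logical()),
      branch_points = data.frame(node_id = integer(), x = numeric(),
                                 y = numeric(), z = numeric(),
                                 order = integer(), n_daughters = integer(),
                                 t1 = integer(), t2 = integer(),
                                 partition_asymmetry = numeric(),
                                 radial_distance_um = numeric()),
      segments = data.frame(node_id = integer(), x0 = numeric(),
                            y0 = numeric(), z0 = numeric(), x1 = numeric(),
                            y1 = numeric(), z1 = numeric(),
                            length_um = numeric(), order = integer(),
                            branch_id = integer()))
    return(structure(empty, class = "branch_set"))
  }

  xyz <- as.matrix(n[, c("x", "y", "z")])
  # vector accumulators (data.frames are assembled once at the end)
  b_order <- integer(); b_start <- integer(); b_end <- integer()
  b_nodes <- integer(); b_plen <- numeric(); b_elen <- numeric()
  b_term <- logical()
  p_row <- integer(); p_order <- integer(); p_ndau <- integer()
  p_t1 <- integer(); p_t2 <- integer()
  seg_node <- vector("list", 64L); seg_order <- integer()
  seg_branch <- integer(); seg_k <- 0L
  bid <- 0L
  # stack entries: (attachment row, first node row of branch, order)
  root_rows <- match(tree$basal_roots, n$id)
  stack <- lapply(root_rows, function(r) c(idx$ppos[r], r, 1L))
  while (length(stack)) {
    e <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    attach_row <- e[1]; row <- e[2]; ord <- e[3]
    bid <- bid + 1L
    path_rows <- row
    while (idx$child_count[row] == 1L) {
      row <- idx$children[[row]][1L]
      path_rows <- c(path_rows, row)
    }
    pts <- xyz[c(attach_row, path_rows), , drop = FALSE]
    d <- diff(pts)
    path_len <- sum(sqrt(rowSums(d^2)))
    euclid <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
    kids <- idx$children[[row]]
    is_terminal <- length(kids) == 0L
    b_order[bid] <- ord; b_start[bid] <- attach_row; b_end[bid] <- row
    b_nodes[bid] <- length(path_rows); b_plen[bid] <- path_len
    b_elen[bid] <- euclid; b_term[bid] <- is_terminal
    seg_k <- seg_k + 1L
    seg_node[[seg_k]] <- path_rows
    seg_order[seg_k] <- ord; seg_branch[seg_k] <- bid
    if (!is_terminal) {
      tc <- idx$tips[kids]
      bif <- length(kids) == 2L
      j <- length(p_row) + 1L
      p_row[j] <- row; p_order[j] <- ord; p_ndau[j] <- length(kids)
      p_t1[j] <- if (bif) tc[1L] else NA_integer_
      p_t2[j] <- if (bif) tc[2L] else NA_integer_
      for (k in kids) stack[[length(stack) + 1L]] <- c(row, k, ord + 1L)
    }
  }
  branches <- data.frame(
    branch_id = seq_len(bid), order = b_order, start_id = n$id[b_start],
    end_id = n$id[b_end], n_nodes = b_nodes, path_length_um = b_plen,
    euclidean_length_um = b_elen,
    contraction = ifelse(b_plen > 0, b_elen / b_plen, NA_real_),
    is_terminal = b_term)
  ctr <- tree$soma_centroid
  bif <- !is.na(p_t1)
  pa <- rep(NA_real_, length(p_row))
  if (any(bif)) pa[bif] <- partition_asymmetry(p_t1[bif], p_t2[bif])
  branch_points <- data.frame(
    node_id = n$id[p_row], x = n$x[p_row], y = n$y[p_row], z = n$z[p_row],
    order = p_order, n_daughters = p_ndau, t1 = p_t1, t2 = p_t2,
    partition_asymmetry = pa,
    radial_distance_um = sqrt((n$x[p_row] - ctr[1])^2 +
                                (n$y[p_row] - ctr[2])^2 +
                                (n$z[p_row] - ctr[3])^2))
  seg_rows <- unlist(seg_node[seq_len(seg_k)])
  seg_ord_full <- rep(seg_order[seq_len(seg_k)],
                      lengths(seg_node[seq_len(seg_k)]))
  seg_bid_full <- rep(seg_branch[seq_len(seg_k)],
                      lengths(seg_node[seq_len(seg_k)]))
  prow <- idx$ppos[seg_rows]
  segments <- data.frame(
    node_id = n$id[seg_rows],
    x0 = n$x[prow], y0 = n$y[prow], z0 = n$z[prow],
    x1 = n$x[seg_rows], y1 = n$y[seg_rows], z1 = n$z[seg_rows],
    order = seg_ord_full, branch_id = seg_bid_full)
  segments$length_um <- sqrt((segments$x1 - segments$x0)^2 +
                             (segments$y1 - segments$y0)^2 +
                             (segments$z1 - segments$z0)^2)
  structure(list(branches = branches, branch_points = branch_points,
                 segments = segments),
            class = "branch_set")
}

#' Maximum radial distance of the basal arbor
#'
#' Greatest Euclidean distance from the soma centroid reached by any
#' basal dendrite compartment.
#'
#' @param tree a [neuron_tree()].
#' @return Distance in micrometres (0 for a tree with no basal nodes).
#' @export
max_radial_distance <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  bs <- tryCatch(extract_branches(tree), warning = function(w) NULL)
  if (is.null(bs)) return(0)
  .max_radial_from_segments(bs$segments, tree$soma_centroid)
}

.max_radial_from_segments <- function(segments, ctr) {
  if (nrow(segments) == 0L) return(0)
  max(sqrt((segments$x1 - ctr[1])^2 + (segments$y1 - ctr[2])^2 +
             (segments$z1 - ctr[3])^2))
}

#' Per-branch-order morphometry
#'
#' Aggregates [extract_branches()] output by centrifugal branch order:
#' branch, branch-point and tip counts, total and mean branch length,
#' mean contraction, and mean partition asymmetry (bifurcations only).
#'
#' @param tree a [neuron_tree()].
#' @return A data.frame of class `branch_order_profile`, one row per
#'   order, with attributes `n_primary` and `max_order`.
#' @export
branch_order_profile <- function(tree) {
  bs <- extract_branches(tree)
  br <- bs$branches
  if (nrow(br) == 0L) {
    out <- data.frame(order = integer(), n_branches = integer(),
                      n_branch_points = integer(), n_tips = integer(),
                      total_length_um = numeric(),
                      mean_branch_length_um = numeric(),
                      mean_contraction = numeric(),
                      mean_partition_asymmetry = numeric())
    return(structure(out, class = c("branch_order_profile", "data.frame"),
                     n_primary = 0L, max_order = 0L))
  }
  orders <- seq_len(max(br$order))
  bp <- bs$branch_points
  out <- data.frame(
    order = orders,
    n_branches = vapply(orders, function(k) sum(br$order == k), integer(1)),
    n_branch_points = vapply(orders, function(k) sum(bp$order == k),
                             integer(1)),
    n_tips = vapply(orders, function(k) sum(br$order == k & br$is_terminal),
                    integer(1)),
    total_length_um = vapply(orders, function(k)
      sum(br$path_length_um[br$order == k]), numeric(1)))
  out$mean_branch_length_um <- out$total_length_um / out$n_branches
  out$mean_contraction <- vapply(orders, function(k)
    mean(br$contraction[br$order == k], na.rm = TRUE), numeric(1))
  out$mean_partition_asymmetry <- vapply(orders, function(k) {
    v <- bp$partition_asymmetry[bp$order == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  structure(out, class = c("branch_order_profile", "data.frame"),
            n_primary = sum(br$order == 1L), max_order = max(br$order))
}

#' Whole-cell scalar morphometry
#'
#' Convenience summary of the quantities compared at the cell level:
#' total basal cable length, total branch points, primary dendrite
#' count, tip count, mean branch length, mean contraction, maximum
#' branch order and maximum radial distance.
#'
#' @param tree a [neuron_tree()].
#' @return A one-row data.frame.
#' @export
neuron_summary <- function(tree) {
  bs <- extract_branches(tree)
  br <- bs$branches
  data.frame(
    cell_id = tree$cell_id, animal_id = tree$animal_id,
    genotype = tree$genotype,
    total_length_um = sum(br$path_length_um),
    n_branch_points = nrow(bs$branch_points),
    n_primary = sum(br$order == 1L),
    n_tips = sum(br$is_terminal),
    n_branches = nrow(br),
    mean_branch_length_um = if (nrow(br)) mean(br$path_length_um) else NA_real_,
    mean_contraction = if (nrow(br)) mean(br$contraction, na.rm = TRUE)
                       else NA_real_,
    max_branch_order = if (nrow(br)) max(br$order) else 0L,
    max_radial_distance_um = .max_radial_from_segments(bs$segments,
                                                       tree$soma_centroid))
}
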