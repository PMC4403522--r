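# fixture builders shared across test files

node_df <- function(...) {
  m <- rbind(...)
  data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
             z = m[, 5], radius = m[, 6], parent = m[, 7])
}

# soma at origin plus one straight basal dendrite along +x
straight_tree <- function(length_um = 25, step = 5) {
  xs <- seq(step, length_um, by = step)
  nodes <- node_df(c(1, 1, 0, 0, 0, 5, -1))
  for (i in seq_along(xs))
    nodes <- rbind(nodes, data.frame(id = i + 1, type = 3, x = xs[i],
                                     y = 0, z = 0, radius = 1,
                                     parent = i))
  neuron_tree(nodes, cell_id = "straight")
}

# primary (2 nodes along +x) that bifurcates into two terminal daughters
y_tree <- function(branch_len = 10) {
  node_df(
    c(1, 1, 0, 0, 0, 5, -1),
    c(2, 3, branch_len / 2, 0, 0, 1, 1),
    c(3, 3, branch_len, 0, 0, 1, 2),
    c(4, 3, branch_len, branch_len / 2, 0, 1, 3),
    c(5, 3, branch_len, branch_len, 0, 1, 4),
    c(6, 3, branch_len, -branch_len / 2, 0, 1, 3),
    c(7, 3, branch_len, -branch_len, 0, 1, 6)) |> neuron_tree(cell_id = "y")
}

# random binary basal tree on a single primary with exactly n_bif
# bifurcations; geometry is an arbitrary jittered walk
random_binary_tree <- function(n_bif, seed = 1) {
  set.seed(seed)
  nodes <- node_df(c(1, 1, 0, 0, 0, 5, -1),
                   c(2, 3, 10, 0, 0, 1, 1))
  tips <- 2L            # node ids that are current tips
  next_id <- 3L
  for (b in seq_len(n_bif)) {
    parent <- if (length(tips) == 1L) tips else sample(tips, 1L)
    tips <- setdiff(tips, parent)
    prow <- nodes[nodes$id == parent, ]
    for (j in 1:2) {
      pos <- c(prow$x, prow$y, prow$z) + stats::rnorm(3, sd = 6)
      nodes <- rbind(nodes, data.frame(id = next_id, type = 3,
                                       x = pos[1], y = pos[2], z = pos[3],
                                       radius = 1, parent = parent))
      tips <- c(tips, next_id)
      next_id <- next_id + 1L
    }
  }
  neuron_tree(nodes, cell_id = sprintf("rand%d", seed))
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rigid rotation about the soma centroid (+ optional translation)
transform_tree <- function(tree, R = diag(3), shift = c(0, 0, 0)) {
  n <- tree$nodes
  ctr <- tree$soma_centroid
  xyz <- t(R %*% t(as.matrix(n[, c("x", "y", "z")]) -
                     matrix(ctr, nrow(n), 3, byrow = TRUE)))
  xyz <- xyz + matrix(ctr + shift, nrow(n), 3, byrow = TRUE)
  n$x <- xyz[, 1]; n$y <- xyz[, 2]; n$z <- xyz[, 3]
  neuron_tree(n, cell_id = tree$cell_id)
}

# independent centrifugal order labelling: order of a basal node is one
# plus the number of multi-child basal ancestors strictly before it
oracle_max_order <- function(tree) {
  n <- tree$nodes
  kids <- table(factor(n$parent, levels = n$id))
  ord <- rep(NA_integer_, nrow(n))
  for (i in seq_len(nrow(n))) {
    if (n$type[i] != 3) next
    o <- 1L
    p <- n$parent[i]
    while (p != -1) {
      prow <- which(n$id == p)
      if (n$type[prow] == 1) break
      if (kids[as.character(p)] >= 2L) o <- o + 1L
      p <- n$parent[prow]
    }
    ord[i] <- o
  }
  max(ord, na.rm = TRUE)
}
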