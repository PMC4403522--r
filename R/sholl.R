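# Split one segment into radially monotone pieces and distribute its
# length over concentric shells of width w centred at the origin.
# a, b: endpoints relative to the shell centre.  Returns a list with
# parallel vectors `shell` and `len`, or NULL for a zero-length segment.
.split_segment <- function(a, b, w) {
  d <- b - a
  L2 <- sum(d * d)
  if (L2 == 0) return(NULL)
  L <- sqrt(L2)
  ad <- sum(a * d)
  aa <- sum(a * a)
  r_of <- function(t) sqrt(aa + 2 * t * ad + t * t * L2)
  tstar <- -ad / L2
  cuts <- c(0, if (tstar > 0 && tstar < 1) tstar, 1)
  shell <- integer(); len <- numeric()
  for (i in seq_len(length(cuts) - 1L)) {
    t0 <- cuts[i]; t1 <- cuts[i + 1L]
    r0 <- r_of(t0); r1 <- r_of(t1)
    k_lo <- floor(min(r0, r1) / w)
    k_hi <- floor(max(r0, r1) / w)
    if (k_hi > k_lo) {
      Rs <- (seq.int(k_lo + 1L, k_hi)) * w
      # radius is monotone on the piece, so each boundary has one root here
      disc <- pmax(ad * ad - L2 * (aa - Rs * Rs), 0)
      root <- sqrt(disc)
      ts <- if (r1 >= r0) (-ad + root) / L2 else rev((-ad - root) / L2)
      ts <- pmin(pmax(ts, t0), t1)
      bounds <- c(t0, ts, t1)
    } else {
      bounds <- c(t0, t1)
    }
    dt <- diff(bounds)
    mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
    keep <- dt > 0
    if (any(keep)) {
      shell <- c(shell, as.integer(floor(r_of(mids[keep]) / w)))
      len <- c(len, L * dt[keep])
    }
  }
  if (length(shell)) list(shell = shell, len = len) else NULL
}

#' Sholl profile of the basal arbor
#'
#' Distributes basal dendritic cable over concentric spherical shells
#' centred on the soma centroid.  Each compartment is split analytically
#' where it crosses shell spheres, so total cable length is conserved
#' exactly (no midpoint binning).  Shells are half-open
#' `[k*w, (k+1)*w)`; a branch point lying exactly on a boundary belongs
#' to the outer shell.  Per shell the profile reports total branch
#' length, the number of branch points, and the maximum centrifugal
#' branch order among compartments intersecting the shell (not only
#' branch points inside it).  Shell 0 (the first `w` micrometres) is
#' always emitted; reporting may drop it.
#'
#' @param tree a [neuron_tree()].
#' @param shell_width shell spacing in micrometres (default 10).
#' @return A data.frame of class `sholl_profile`, one row per shell from
#'   the soma outward: `shell` (0-based index), `r_lo`, `r_hi`,
#'   `length_um`, `cumulative_length_um`, `n_branch_points`,
#'   `max_order`.  Attributes: `shell_width`, `max_radial_distance_um`,
#'   `total_length_um`, `total_branch_points`.
#' @export
sholl_profile <- function(tree, shell_width = 10) {
  stopifnot(inherits(tree, "neuron_tree"), shell_width > 0)
  bs <- extract_branches(tree)
  seg <- bs$segments
  ctr <- tree$soma_centroid
  if (nrow(seg) == 0L) {
    out <- data.frame(shell = integer(), r_lo = numeric(), r_hi = numeric(),
                      length_um = numeric(), cumulative_length_um = numeric(),
                      n_branch_points = integer(), max_order = integer())
    return(structure(out, class = c("sholl_profile", "data.frame"),
                     shell_width = shell_width, max_radial_distance_um = 0,
                     total_length_um = 0, total_branch_points = 0L))
  }
  x0 <- seg$x0 - ctr[1]; y0 <- seg$y0 - ctr[2]; z0 <- seg$z0 - ctr[3]
  x1 <- seg$x1 - ctr[1]; y1 <- seg$y1 - ctr[2]; z1 <- seg$z1 - ctr[3]
  p_shell <- vector("list", nrow(seg))
  p_len <- vector("list", nrow(seg))
  p_ord <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    sp <- .split_segment(c(x0[i], y0[i], z0[i]),
                         c(x1[i], y1[i], z1[i]), shell_width)
    if (!is.null(sp)) {
      p_shell[[i]] <- sp$shell
      p_len[[i]] <- sp$len
      p_ord[[i]] <- rep(seg$order[i], length(sp$shell))
    }
  }
  pc_shell <- unlist(p_shell); pc_len <- unlist(p_len)
  pc_ord <- unlist(p_ord)
  n_shell <- max(pc_shell) + 1L
  f <- factor(pc_shell, levels = seq_len(n_shell) - 1L)
  len <- as.numeric(tapply(pc_len, f, sum, default = 0))
  max_ord <- as.integer(tapply(pc_ord, f, max, default = NA_integer_))
  bp_r <- bs$branch_points$radial_distance_um
  bp_shell <- floor(bp_r / shell_width)
  nbp <- vapply(seq_len(n_shell) - 1L, function(k) sum(bp_shell == k),
                integer(1))
  node_r <- sqrt((seg$x1 - ctr[1])^2 + (seg$y1 - ctr[2])^2 +
                   (seg$z1 - ctr[3])^2)
  out <- data.frame(shell = seq_len(n_shell) - 1L,
                    r_lo = (seq_len(n_shell) - 1L) * shell_width,
                    r_hi = seq_len(n_shell) * shell_width,
                    length_um = len,
                    cumulative_length_um = cumsum(len),
                    n_branch_points = nbp,
                    max_order = max_ord)
  structure(out, class = c("sholl_profile", "data.frame"),
            shell_width = shell_width,
            max_radial_distance_um = max(node_r),
            total_length_um = sum(seg$length_um),
            total_branch_points = nrow(bs$branch_points))
}
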