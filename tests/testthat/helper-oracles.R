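# independent statistical oracles used by the unit and acceptance tests

# balanced mixed-design sums of squares, written out longhand
oracle_rm_anova <- function(pm) {
  units <- unique(pm$unit)
  G <- length(unique(pm$genotype))
  L <- length(unique(pm$level))
  N <- length(units)
  grand <- mean(pm$value)
  mean_unit <- tapply(pm$value, pm$unit, mean)
  mean_g <- tapply(pm$value, pm$genotype, mean)
  mean_l <- tapply(pm$value, pm$level, mean)
  mean_gl <- tapply(pm$value, list(pm$genotype, pm$level), mean)
  n_per_g <- N / G
  ss_total <- sum((pm$value - grand)^2)
  ss_between <- L * sum((mean_unit - grand)^2)
  ss_g <- L * n_per_g * sum((mean_g - grand)^2)
  ss_subj <- ss_between - ss_g
  ss_l <- N * sum((mean_l - grand)^2)
  ss_gl <- n_per_g * sum((sweep(sweep(mean_gl, 1, mean_g), 2, mean_l) +
                            grand)^2)
  ss_err <- ss_total - ss_between - ss_l - ss_gl
  list(F_genotype = (ss_g / (G - 1)) / (ss_subj / (N - G)),
       F_level = (ss_l / (L - 1)) / (ss_err / ((N - G) * (L - 1))),
       F_interaction = (ss_gl / ((G - 1) * (L - 1))) /
         (ss_err / ((N - G) * (L - 1))))
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  idx <- utils::combn(length(pooled), m)
  ustat <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- ustat(a, b)
  us <- apply(idx, 2, function(ii) ustat(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# exact two-sided signed-rank p by enumeration of all sign patterns
oracle_wsr_p <- function(d) {
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}
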