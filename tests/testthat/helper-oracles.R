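# Independent oracles, kept free of package internals.

# exact two-sided Wilcoxon rank-sum p by full enumeration of all group-label
# assignments of the pooled sample (assumes no ties)
enumerate_wilcoxon_p <- function(a, w) {
  pooled <- c(a, w)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(stats - mu) >= abs(w_obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up by hand
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# brute-force pseudo-residue dD-bar: per residue, per timepoint, loop over
# covering peptides and average, then difference and average over timepoints
brute_force_dD <- function(upt_var, upt_ref, coverage) {
  peps <- intersect(upt_var$peptide_id, upt_ref$peptide_id)
  tps <- intersect(upt_var$timepoint, upt_ref$timepoint)
  res <- list()
  for (key in names(coverage)) {
    pids <- intersect(coverage[[key]], peps)
    if (length(pids) == 0) next
    dsum <- 0
    for (tp in tps) {
      fv <- fr <- c()
      for (pid in pids) {
        fv <- c(fv, upt_var$fraction_of_max[upt_var$peptide_id == pid &
                                              upt_var$timepoint == tp])
        fr <- c(fr, upt_ref$fraction_of_max[upt_ref$peptide_id == pid &
                                              upt_ref$timepoint == tp])
      }
      dsum <- dsum + 100 * (mean(fv) - mean(fr))
    }
    res[[key]] <- dsum / length(tps)
  }
  res
}

# O(n^2) selection-sort oracle for hotspot ranking: repeatedly extract the
# lexicographic max of (frequency desc, accession asc, position asc)
brute_force_rank_order <- function(freq, acc, pos) {
  keys <- data.frame(f = -freq, a = acc, p = pos, stringsAsFactors = FALSE)
  remaining <- seq_along(freq)
  out <- integer(0)
  while (length(remaining)) {
    best <- remaining[1]
    for (i in remaining)
      if (keys$f[i] < keys$f[best] ||
          (keys$f[i] == keys$f[best] && (keys$a[i] < keys$a[best] ||
            (keys$a[i] == keys$a[best] && keys$p[i] < keys$p[best]))))
        best <- i
    out <- c(out, best)
    remaining <- setdiff(remaining, best)
  }
  out
}

# rotation matrix about a unit axis by angle (for the grid-search oracle)
axis_angle_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

# best RMSD over a dense grid of rotations (centered coordinates), an
# exhaustive stand-in for the Kabsch optimum on tiny problems
grid_search_rmsd <- function(x, y, n_axis = 200, n_angle = 180) {
  x0 <- sweep(x, 2, colMeans(x))
  y0 <- sweep(y, 2, colMeans(y))
  best <- Inf
  set.seed(42)
  axes <- matrix(rnorm(3 * n_axis), ncol = 3)
  angles <- seq(0, 2 * pi, length.out = n_angle)
  for (i in seq_len(n_axis)) {
    for (th in angles) {
      r <- axis_angle_rotation(axes[i, ], th)
      d <- y0 %*% t(r) - x0
      best <- min(best, sqrt(mean(rowSums(d^2))))
    }
  }
  best
}
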