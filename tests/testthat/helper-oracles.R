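# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (loops, enumeration, direct
# formulas) and never call the package's own implementation paths.

# Breadth-first search distances over an undirected edge list
bfs_levels <- function(edges, root) {
  areas <- sort(unique(c(edges$area_a, edges$area_b)))
  adj <- lapply(stats::setNames(areas, areas), function(a) {
    unique(c(edges$area_b[edges$area_a == a], edges$area_a[edges$area_b == a]))
  })
  dist <- stats::setNames(rep(NA_integer_, length(areas)), areas)
  dist[root] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Step-up Benjamini-Hochberg keep set and adjusted values by direct rule
bh_brute <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  thresh <- which(ps <= seq_len(m) * q / m)
  keep <- rep(FALSE, m)
  if (length(thresh)) keep[ord[seq_len(max(thresh))]] <- TRUE
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  p_fdr <- numeric(m)
  p_fdr[ord] <- adj
  list(keep = keep, p_fdr = p_fdr)
}

# ICC(3,1) via the two-way ANOVA decomposition from aov()
icc31_aov <- function(day1, day2) {
  n <- length(day1)
  d <- data.frame(y = c(day1, day2),
                  subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][, "Mean Sq"]
  bms <- ms[1]; ems <- ms[3]
  (bms - ems) / (bms + ems)
}

# OLS coefficients by explicit normal equations
ols_brute <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Mantel R^2 statistic by explicit double loop over lower-triangle entries
mantel_r2_brute <- function(m1, m2) {
  va <- c(); vb <- c()
  R <- nrow(m1)
  for (i in 2:R) for (j in 1:(i - 1)) {
    if (is.finite(m1[i, j]) && is.finite(m2[i, j])) {
      va <- c(va, m1[i, j]); vb <- c(vb, m2[i, j])
    }
  }
  stats::cor(va, vb)^2
}

# small twin cohort shared by several tests
small_cohort <- function(n_mz = 30, n_dz = 20, seed = 11) {
  generate_pedigree(n_mz, n_dz, seed = seed)
}

# single-hemisphere analysis graph used by the deeper pipeline tests
lh_graph <- function() {
  fix <- visual_graph_fixture()
  keep <- grep("^lh_", fix$areas, value = TRUE)
  generate_area_graph(fix$edges[fix$edges$area_a %in% keep &
                                  fix$edges$area_b %in% keep, ])
}
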