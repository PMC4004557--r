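# Fixtures shared across test files; everything is generated in code.

# Bimodal image: two plateaus at levels 3 and 12 (of 15) with salt noise.
bimodal_image <- function(seed = 6, salt = 0.05, n = 32) {
  set.seed(seed)
  img <- matrix(3 / 15, n, n)
  img[, (n / 2 + 1):n] <- 12 / 15
  sel <- matrix(stats::runif(n * n) < salt, n, n)
  img[sel] <- stats::runif(sum(sel))
  img
}

# Horizontal bright Gaussian ridge of cross-section scale sigma_v.
gaussian_ridge <- function(n = 64, sigma_v = 2, row = n / 2) {
  ys <- matrix(rep(seq_len(n), n), n)
  exp(-(ys - row)^2 / (2 * sigma_v^2))
}

# 45-degree Gaussian ridge along the main diagonal.
gaussian_ridge_45 <- function(n = 64, sigma_v = 2) {
  ys <- matrix(rep(seq_len(n), n), n)
  xs <- t(ys)
  d <- (ys - xs) / sqrt(2)
  exp(-d^2 / (2 * sigma_v^2))
}

# Region graph of two k-cliques (intra-weight 1) joined by one weak edge.
two_clique_graph <- function(weak = 0.01) {
  edges <- NULL
  for (i in 1:4) for (j in (i + 1):5) edges <- rbind(edges, c(i, j, 1))
  for (i in 6:9) for (j in (i + 1):10) edges <- rbind(edges, c(i, j, 1))
  edges <- rbind(edges, c(5, 6, weak))
  edges <- data.frame(a = edges[, 1], b = edges[, 2], weight = edges[, 3])
  structure(list(features = matrix(0, 10, 1), features_std = matrix(0, 10, 1),
                 edges = edges, n = 10),
            class = "region_graph")
}

# Apply a node permutation to a region graph.
permute_graph <- function(graph, perm) {
  g <- graph
  g$edges$a <- perm[graph$edges$a]
  g$edges$b <- perm[graph$edges$b]
  swap <- g$edges$a > g$edges$b
  tmp <- g$edges$a[swap]; g$edges$a[swap] <- g$edges$b[swap]; g$edges$b[swap] <- tmp
  g$features_std <- graph$features_std[order(perm), , drop = FALSE]
  g
}

# Naive quadrant-loop second-order entropy oracle (renormalised, log2, 1/2).
naive_entropy_curve <- function(P, L) {
  hq <- function(sub) {
    p <- sub[sub > 0]
    if (!length(p)) return(0)
    ph <- p / sum(p)
    -0.5 * sum(ph * log2(ph))
  }
  vapply(0:(L - 1), function(t) {
    hq(P[1:(t + 1), 1:(t + 1), drop = FALSE]) +
      hq(P[(t + 2):(L + 1), (t + 2):(L + 1), drop = FALSE])
  }, numeric(1))
}

count_components8 <- function(mask) max(retseg:::label8(mask))
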