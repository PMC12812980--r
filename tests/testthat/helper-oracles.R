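# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# Benjamini-Hochberg by the literal sort definition: for each p, q is the
# smallest m*p_(j)/j over all sorted p_(j) >= p.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Spearman rho from first principles: average ranks, then the explicit
# Pearson formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# Diameter and mean path length on the largest connected component, from the
# Floyd-Warshall distances.
oracle_path_metrics <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  comp_of <- ifelse(is.infinite(d), 0, 1)
  # connected components from reachability
  members <- lapply(seq_len(nrow(d)), function(i) which(is.finite(d[i, ])))
  sizes <- lengths(members)
  giant <- members[[which.max(sizes)]]
  dg <- d[giant, giant, drop = FALSE]
  off <- dg[upper.tri(dg)]
  list(diameter = if (length(off)) max(off) else 0,
       avg_path_length = if (length(off)) mean(off) else 0)
}

# All set partitions of 1..n as membership vectors (restricted growth).
oracle_partitions <- function(n) {
  out <- list()
  grow <- function(memb, mx) {
    k <- length(memb)
    if (k == n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (g in seq_len(mx + 1)) grow(c(memb, g), max(mx, g))
  }
  grow(1L, 1L)
  out
}

# Exhaustive maximum Newman modularity over every partition of the nodes.
oracle_best_modularity <- function(g) {
  parts <- oracle_partitions(igraph::vcount(g))
  max(vapply(parts, function(memb) igraph::modularity(g, memb), 1))
}

# Exact Mantel p-value by enumerating all n! joint relabelings of d2.
oracle_mantel_exact <- function(d1, d2, method = "spearman") {
  n <- nrow(d1)
  v1 <- d1[upper.tri(d1)]
  if (method == "spearman") v1 <- rank(v1)
  corfun <- function(dd) {
    v2 <- dd[upper.tri(dd)]
    if (method == "spearman") v2 <- rank(v2)
    cor(v1, v2)
  }
  perms <- gtools_permutations(n)
  rs <- apply(perms, 1, function(idx) corfun(d2[idx, idx]))
  obs <- corfun(d2)
  mean(rs >= obs - 1e-12)
}

# plain recursive permutation enumeration (no package dependence)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Bray-Curtis between two vectors, elementwise definition.
oracle_bray <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# Random Erdos-Renyi-ish adjacency with optional guaranteed edge.
random_adjacency <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- rbinom(length(up), 1, p)
  adj <- adj + t(adj)
  adj
}

# Build a cooccurrence_network object directly from an adjacency matrix so
# topology metrics can be tested on exactly known graphs.
network_from_adjacency <- function(adj, kingdom = NULL, signs = NULL, group = NA_character_) {
  n <- nrow(adj)
  ids <- sprintf("t%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  kingdom <- kingdom %||% rep(c("phytoplankton", "bacteria"), length.out = n)
  edges <- tibble::tibble(
    taxon_i = ids[idx[, 1]],
    taxon_j = ids[idx[, 2]],
    rho = rep(0.9, nrow(idx)),
    p = rep(1e-6, nrow(idx)),
    q = rep(1e-5, nrow(idx)),
    sign = if (is.null(signs)) rep("+", nrow(idx)) else signs
  )
  structure(
    list(
      nodes = tibble::tibble(taxon_id = ids, kingdom = kingdom,
                             phylum = rep(NA_character_, n)),
      edges = edges,
      group = group, threshold_r = 0.6, alpha = 0.05, n_samples = 30
    ),
    class = "cooccurrence_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-kingdom count fixture with deterministic structure.
toy_counts <- function() {
  tibble::tibble(
    taxon_id = c("p1", "p2", "p3", "b1", "b2", "b3"),
    s1 = c(10, 20, 5, 100, 200, 50),
    s2 = c(20, 40, 2, 200, 400, 20),
    s3 = c(30, 60, 9, 300, 600, 90),
    s4 = c(5, 10, 4, 50, 100, 40),
    s5 = c(40, 80, 7, 400, 800, 70)
  )
}

toy_taxonomy <- function() {
  tibble::tibble(
    taxon_id = c("p1", "p2", "p3", "b1", "b2", "b3"),
    kingdom = c(rep("phytoplankton", 3), rep("bacteria", 3)),
    phylum = c("Bacillariophyta", "Bacillariophyta", "Cyanophyta",
               "Proteobacteria", "Proteobacteria", "Bacteroidota"),
    genus = paste0("g_", c("p1", "p2", "p3", "b1", "b2", "b3"))
  )
}

# Random distance matrix from points on a line.
random_distance <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.matrix(dist(rnorm(n)))
}
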