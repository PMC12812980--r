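test_that("abundance filter applies the strict per-kingdom threshold", {
  # grand total 10000 within the kingdom: 0.02% kept, exactly 0.01% dropped
  counts <- tibble::tibble(taxon_id = c("keep", "drop", "big"),
                           s1 = c(1, 1, 4999), s2 = c(1, 0, 4998))
  tax <- tibble::tibble(taxon_id = c("keep", "drop", "big"),
                        kingdom = rep("bacteria", 3), phylum = "x")
  out <- filter_low_abundance(counts, tax, min_rel = 1e-4)
  expect_equal(out$taxon_id, c("keep", "big"))
  # all above threshold: identity, order preserved
  even <- tibble::tibble(taxon_id = c("a", "b"), s1 = c(5, 5))
  expect_identical(filter_low_abundance(even)$taxon_id, c("a", "b"))
  expect_error(filter_low_abundance(even, min_rel = 0.9), "no taxon")
  # kingdoms use separate grand totals
  mixed <- tibble::tibble(taxon_id = c("p", "b_small", "b_big"),
                          s1 = c(10, 2, 9998))
  tax2 <- tibble::tibble(taxon_id = c("p", "b_small", "b_big"),
                         kingdom = c("phytoplankton", "bacteria", "bacteria"),
                         phylum = "x")
  out2 <- filter_low_abundance(mixed, tax2, min_rel = 1e-4)
  expect_true(all(c("p", "b_small") %in% out2$taxon_id))
})

test_that("network edges obey the double gate and carry the correlation sign", {
  set.seed(61)
  # p1 and b1 rise with a shared driver, b2 falls with it, b3 and p2 are
  # stable; the per-kingdom relative-abundance transform keeps the ranks
  # because each kingdom contains a stable reference taxon
  n <- 12
  base <- rnorm(n)
  eps <- function() exp(rnorm(n, 0, 0.03))
  counts <- tibble::tibble(
    taxon_id = c("p1", "p2", "b1", "b2", "b3"),
    !!!setNames(as.list(as.data.frame(rbind(
      100 * exp(base) * eps(), 100 * eps(), 100 * exp(base) * eps(),
      100 * exp(-base) * eps(), 100 * eps()
    ))), paste0("s", seq_len(n)))
  )
  tax <- tibble::tibble(taxon_id = counts$taxon_id,
                        kingdom = c("phytoplankton", "phytoplankton", rep("bacteria", 3)),
                        phylum = "x")
  net <- build_network(counts, tax, group = "L")
  key <- function(e) paste(e$taxon_i, e$taxon_j, e$sign)
  expect_true("p1 b1 +" %in% key(net$edges))
  expect_true("p1 b2 -" %in% key(net$edges))
  expect_true("b1 b2 -" %in% key(net$edges))
  # double gate re-verified edge by edge post hoc
  rel <- counts
  rel[1:2, -1] <- sweep(as.matrix(counts[1:2, -1]), 2, colSums(as.matrix(counts[1:2, -1])), "/")
  rel[3:5, -1] <- sweep(as.matrix(counts[3:5, -1]), 2, colSums(as.matrix(counts[3:5, -1])), "/")
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    x <- as.numeric(rel[rel$taxon_id == e$taxon_i, -1])
    y <- as.numeric(rel[rel$taxon_id == e$taxon_j, -1])
    expect_gte(abs(spearman_rho(x, y)), net$threshold_r)
    expect_lt(e$q, net$alpha)
    expect_equal(e$sign, ifelse(e$rho >= 0, "+", "-"))
  }
  expect_error(build_network(counts[, 1:4], tax), "at least 4 samples")
  expect_warning(build_network(counts[3:5, ], tax[3:5, ]), "one kingdom")
})

test_that("a planted two-block copula fixture is recovered", {
  # one correlated block of 5 taxa per kingdom (within latent r = 0.9, none
  # between kingdoms) over 30 samples, embedded among independent background
  # taxa heavy enough that the block is a minor share of its kingdom total
  set.seed(71)
  n <- 30; k <- 5; bg <- 5
  make_kingdom <- function() {
    f <- rnorm(n)
    block <- sapply(seq_len(k), function(i) sqrt(0.9) * f + sqrt(0.1) * rnorm(n))
    noise <- matrix(rnorm(n * bg), n, bg)
    cbind(matrix(qnbinom(pnorm(block), mu = 100, size = 8), n, k),
          matrix(qnbinom(pnorm(noise), mu = 600, size = 8), n, bg))
  }
  counts_m <- cbind(make_kingdom(), make_kingdom())
  counts <- dplyr::bind_cols(
    tibble::tibble(taxon_id = paste0("t", seq_len(2 * (k + bg)))),
    tibble::as_tibble(t(counts_m), .name_repair = ~paste0("s", 1:n))
  )
  tax <- tibble::tibble(taxon_id = counts$taxon_id,
                        kingdom = rep(c("phytoplankton", "bacteria"), each = k + bg),
                        phylum = "x")
  net <- build_network(counts, tax)
  block_of <- function(i) ifelse(i <= k, 1L, ifelse(i > k + bg & i <= 2 * k + bg, 2L, 0L))
  idx <- cbind(match(net$edges$taxon_i, counts$taxon_id),
               match(net$edges$taxon_j, counts$taxon_id))
  bi <- block_of(idx[, 1]); bj <- block_of(idx[, 2])
  within_found <- sum(bi > 0 & bi == bj)
  other_found <- sum(!(bi > 0 & bi == bj))
  n_pairs <- choose(2 * (k + bg), 2)
  expect_gte(within_found / (2 * choose(k, 2)), 0.9)       # >= 90% of planted pairs
  expect_lte(other_found / (n_pairs - 2 * choose(k, 2)), 0.05)  # < 5% spurious
})

test_that("topology metrics match hand-enumerated graphs", {
  # 4-node path: pairwise distances 1,2,3,1,2,1
  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- 1; path4 <- path4 + t(path4)
  tp <- topology(network_from_adjacency(path4))
  expect_equal(tp$diameter, 3L)
  expect_equal(tp$avg_degree, 1.5)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$avg_path_length, 5 / 3)
  expect_equal(tp$n_components, 1)

  # two disjoint triangles: clustering 1, best two-community modularity 1/2
  tri2 <- matrix(0, 6, 6)
  tri2[cbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4))] <- 1
  tri2 <- pmax(tri2, t(tri2))
  tt <- topology(network_from_adjacency(tri2))
  expect_equal(tt$clustering_coefficient, 1)
  expect_equal(tt$modularity, 0.5, tolerance = 1e-9)
  expect_equal(tt$n_components, 2)
  # disconnected: path metrics on the largest component
  expect_equal(tt$diameter, 1L)
  expect_equal(tt$avg_path_length, 1)

  # complete graph K5
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  tk <- topology(network_from_adjacency(k5))
  expect_equal(tk$clustering_coefficient, 1)
  expect_equal(tk$diameter, 1L)
  expect_equal(tk$modularity, 0, tolerance = 1e-9)
  expect_equal(tk$avg_degree, 4)
})

test_that("signed percentages and empty networks are handled", {
  adj <- matrix(0, 4, 4); adj[1, 2] <- adj[2, 3] <- adj[3, 4] <- 1
  adj <- pmax(adj, t(adj))
  net <- network_from_adjacency(adj, signs = c("+", "-", "-"))
  tp <- topology(net)
  expect_equal(tp$pct_positive_edges + tp$pct_negative_edges, 100)
  expect_equal(tp$pct_negative_edges, 100 * 2 / 3)
  empty <- network_from_adjacency(matrix(0, 3, 3))
  te <- topology(empty)
  expect_true(te$empty)
  expect_equal(te$n_edges, 0L)
  expect_equal(te$modularity, 0)
})

test_that("Louvain modularity attains the exhaustive optimum on small graphs", {
  set.seed(91)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, p = 0.4)
    if (sum(adj) == 0) adj[1, 2] <- adj[2, 1] <- 1
    net <- network_from_adjacency(adj)
    g <- trophicnet:::as_igraph(net)
    expect_equal(topology(net)$modularity, oracle_best_modularity(g), tolerance = 1e-9)
  }
})

test_that("path length and diameter match a Floyd-Warshall oracle", {
  set.seed(101)
  for (n in c(10, 25, 50)) {
    adj <- random_adjacency(n, p = 0.08)
    if (sum(adj) == 0) adj[1, 2] <- adj[2, 1] <- 1
    tp <- topology(network_from_adjacency(adj))
    o <- oracle_path_metrics(adj)
    expect_equal(tp$diameter, as.integer(o$diameter))
    expect_equal(tp$avg_path_length, o$avg_path_length)
  }
})

test_that("topology metrics are invariant to node relabeling", {
  set.seed(111)
  adj <- random_adjacency(12, p = 0.3)
  net <- network_from_adjacency(adj)
  perm <- sample(12)
  net2 <- network_from_adjacency(adj[perm, perm])
  t1 <- topology(net)[, -1]   # drop group label
  t2 <- topology(net2)[, -1]
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("cross-kingdom composition classifies edges by kingdom pair and sign", {
  adj <- matrix(0, 5, 5)
  # nodes alternate phyto/bact: t1 p, t2 b, t3 p, t4 b, t5 p
  adj[2, 4] <- 1   # BB
  adj[1, 3] <- 1   # PP
  adj[1, 2] <- 1   # BP
  adj[3, 4] <- 1   # BP
  adj <- pmax(adj, t(adj))
  net <- network_from_adjacency(adj, kingdom = c("phytoplankton", "bacteria",
                                                 "phytoplankton", "bacteria", "phytoplankton"))
  comp <- cross_kingdom_composition(net)
  bp <- sum(comp$n[comp$pair_type == "BP"])
  expect_equal(bp / sum(comp$n), 0.5)
  expect_equal(sum(comp$n), 4)
  # all-bacterial network: no BP edges, flagged
  netb <- network_from_adjacency(pmax(adj, t(adj)), kingdom = rep("bacteria", 5))
  compb <- cross_kingdom_composition(netb)
  expect_equal(sum(compb$n[compb$pair_type == "BP"]), 0)
  expect_true(attr(compb, "single_kingdom"))
  # unlabeled node is an error naming it
  netna <- net; netna$nodes$kingdom[3] <- NA
  expect_error(cross_kingdom_composition(netna), "t03")
})

test_that("topology comparison flags the cross-gradient trends", {
  mk <- function(g, mod, neg) tibble::tibble(
    group = g, n_nodes = 233L, n_edges = 3000L, avg_degree = 25, diameter = 5L,
    clustering_coefficient = 0.7, modularity = mod, avg_path_length = 2.3,
    pct_positive_edges = 100 - neg, pct_negative_edges = neg,
    n_components = 1, empty = FALSE)
  cmp <- compare_topologies(dplyr::bind_rows(mk("L", 0.641, 0.32), mk("M", 0.598, 0.36), mk("H", 0.558, 0.61)))
  expect_equal(cmp$trend[cmp$metric == "modularity"], "decreasing")
  expect_equal(cmp$trend[cmp$metric == "pct_negative_edges"], "increasing")
  expect_equal(cmp$trend[cmp$metric == "n_nodes"], "flat")
  expect_equal(cmp$delta[cmp$metric == "modularity"], 0.558 - 0.641)
  expect_error(compare_topologies(mk("L", 0.6, 0.3)), "at least 2")
})
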