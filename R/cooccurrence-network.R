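#' Filter taxa by overall relative abundance
#'
#' Retains taxa whose overall relative abundance — taxon total divided by the
#' grand total, computed within each kingdom separately when a taxonomy is
#' supplied — is strictly above `min_rel` (default 0.01%). Row order is
#' preserved. This is the node-selection gate applied to the pooled table
#' before any per-group network is built, so all groups share one node set.
#'
#' @param counts Data frame, first column `taxon_id`, remaining columns counts.
#' @param taxonomy Optional data frame (`taxon_id`, `kingdom`); when present
#'   the grand total is per kingdom.
#' @param min_rel Strict lower threshold on overall relative abundance
#'   (default `1e-4`, i.e. 0.01%).
#' @return The filtered count table (same layout).
#' @export
filter_low_abundance <- function(counts, taxonomy = NULL, min_rel = 1e-4) {
  m <- counts_matrix(counts)
  totals <- rowSums(m)
  if (is.null(taxonomy)) {
    rel <- totals / sum(totals)
  } else {
    kingdom <- setNames(as.character(taxonomy$kingdom), as.character(taxonomy$taxon_id))
    unknown <- setdiff(rownames(m), names(kingdom))
    if (length(unknown)) abort(paste0("taxa missing from taxonomy: ", paste(unknown, collapse = ", ")))
    k <- kingdom[rownames(m)]
    grand <- tapply(totals, k, sum)
    rel <- totals / as.numeric(grand[k])
  }
  keep <- rel > min_rel
  if (!any(keep)) abort("no taxon passes the abundance filter; lower `min_rel`")
  counts[keep, , drop = FALSE]
}

#' Build a signed co-occurrence network
#'
#' Constructs the thresholded Spearman correlation graph over taxa: counts are
#' converted to per-kingdom relative abundances (Spearman's rank invariance
#' then makes cell densities and read counts commensurable), all unordered
#' taxon pairs are correlated across the supplied samples, p-values are
#' FDR-adjusted once over the full pair set, and an edge is retained only when
#' `|rho| >= threshold_r` **and** `q < alpha`. Edge sign is the sign of rho.
#'
#' @param counts Data frame, first column `taxon_id`, remaining columns the
#'   samples of one trophic group (at least 4).
#' @param taxonomy Data frame with columns `taxon_id`, `kingdom` (values
#'   `phytoplankton` / `bacteria`) and optionally `phylum`, `genus`.
#' @param group Optional group label (`"L"`, `"M"`, `"H"`) stored on the
#'   network.
#' @param threshold_r Absolute correlation threshold (default 0.6).
#' @param alpha FDR significance level (default 0.05).
#' @return A `cooccurrence_network`: list with `nodes` (tibble `taxon_id`,
#'   `kingdom`, `phylum`), `edges` (tibble `taxon_i`, `taxon_j`, `rho`, `q`,
#'   `sign`), `group`, `threshold_r`, `alpha`, `n_samples`.
#' @export
build_network <- function(counts, taxonomy, group = NA_character_,
                          threshold_r = 0.6, alpha = 0.05) {
  m <- counts_matrix(counts)
  if (ncol(m) < 4) abort("network construction needs at least 4 samples")
  kingdom <- setNames(as.character(taxonomy$kingdom), as.character(taxonomy$taxon_id))
  unknown <- setdiff(rownames(m), names(kingdom))
  if (length(unknown)) abort(paste0("taxa missing from taxonomy: ", paste(unknown, collapse = ", ")))
  k <- kingdom[rownames(m)]
  bad <- !k %in% c("phytoplankton", "bacteria")
  if (any(bad)) abort(paste0("unknown kingdom for taxa: ", paste(rownames(m)[bad], collapse = ", ")))
  if (length(unique(k)) < 2) {
    warn("only one kingdom present; the network will contain no cross-kingdom edges")
  }
  # per-kingdom relative abundance
  rel <- m
  for (kg in unique(k)) {
    sub <- m[k == kg, , drop = FALSE]
    tot <- colSums(sub)
    if (any(tot <= 0)) {
      abort(paste0("sample(s) with zero ", kg, " total: ",
                   paste(colnames(m)[tot <= 0], collapse = ", ")))
    }
    rel[k == kg, ] <- sweep(sub, 2, tot, "/")
  }
  cors <- correlation_matrix(counts_tibble(rel))
  keep <- !is.na(cors$rho) & abs(cors$rho) >= threshold_r & !is.na(cors$q) & cors$q < alpha
  edges <- cors[keep, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "+", "-")
  phylum <- if ("phylum" %in% names(taxonomy)) {
    setNames(as.character(taxonomy$phylum), as.character(taxonomy$taxon_id))[rownames(m)]
  } else {
    rep(NA_character_, nrow(m))
  }
  structure(
    list(
      nodes = tibble::tibble(taxon_id = rownames(m), kingdom = unname(k), phylum = unname(phylum)),
      edges = tibble::as_tibble(edges),
      group = group,
      threshold_r = threshold_r,
      alpha = alpha,
      n_samples = ncol(m)
    ),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network%s: %d nodes, %d edges (|rho| >= %g, q < %g, n = %d samples)\n",
              if (!is.na(x$group)) paste0(" [", x$group, "]") else "",
              nrow(x$nodes), nrow(x$edges), x$threshold_r, x$alpha, x$n_samples))
  invisible(x)
}

#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

# unsigned simple igraph over the full node set (isolates included)
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("taxon_i", "taxon_j", "rho", "q", "sign")],
    directed = FALSE,
    vertices = network$nodes
  )
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Topology metrics of a co-occurrence network
#'
#' The standard topology bundle on the unsigned simple graph (sign is kept as
#' an edge attribute and used only for the signed percentages): node and edge
#' counts, average degree `2E/N`, diameter and average shortest-path length on
#' the largest connected component, mean local clustering coefficient (nodes
#' of degree < 2 contribute 0), Louvain modularity (best Q over `restarts`
#' seeded runs, resolution 1), percentage of positive and of negative edges,
#' and the number of connected components.
#'
#' @param network A `cooccurrence_network`.
#' @param restarts Louvain restarts (default 10); the best modularity is kept.
#' @param seed Seed for the Louvain restarts.
#' @return A one-row tibble of class `network_topology` with columns `group`,
#'   `n_nodes`, `n_edges`, `avg_degree`, `diameter`, `clustering_coefficient`,
#'   `modularity`, `avg_path_length`, `pct_positive_edges`,
#'   `pct_negative_edges`, `n_components`, `empty`.
#' @export
topology <- function(network, restarts = 10, seed = 1) {
  stopifnot(inherits(network, "cooccurrence_network"))
  n_nodes <- nrow(network$nodes)
  n_edges <- nrow(network$edges)
  if (n_nodes < 1) abort("network has no nodes")
  if (n_edges == 0) {
    out <- tibble::tibble(
      group = network$group, n_nodes = n_nodes, n_edges = 0L, avg_degree = 0,
      diameter = 0L, clustering_coefficient = 0, modularity = 0,
      avg_path_length = 0, pct_positive_edges = 0, pct_negative_edges = 0,
      n_components = n_nodes, empty = TRUE
    )
    class(out) <- c("network_topology", class(out))
    return(out)
  }
  g <- as_igraph(network)
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comps$membership == which.max(comps$csize)))
  clustering <- mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  mod <- louvain_modularity(g, restarts = restarts, seed = seed)
  out <- tibble::tibble(
    group = network$group,
    n_nodes = n_nodes,
    n_edges = n_edges,
    avg_degree = 2 * n_edges / n_nodes,
    diameter = as.integer(igraph::diameter(giant, weights = NA)),
    clustering_coefficient = clustering,
    modularity = mod,
    avg_path_length = igraph::mean_distance(giant, weights = NA),
    pct_positive_edges = 100 * mean(network$edges$sign == "+"),
    pct_negative_edges = 100 * mean(network$edges$sign == "-"),
    n_components = comps$no,
    empty = FALSE
  )
  class(out) <- c("network_topology", class(out))
  out
}

# Best Louvain Q over seeded restarts (unsigned, unweighted, resolution 1).
louvain_modularity <- function(g, restarts = 10, seed = 1) {
  best <- -Inf
  for (i in seq_len(restarts)) {
    cl <- with_stage_seed(seed, paste0("louvain", i),
                          igraph::cluster_louvain(g, weights = NA, resolution = 1))
    q <- igraph::modularity(g, igraph::membership(cl))
    if (q > best) best <- q
  }
  best
}

#' @export
glance.cooccurrence_network <- function(x, ...) topology(x)

#' Cross-kingdom edge composition
#'
#' Classifies every edge of a network as bacteria-bacteria (`BB`),
#' phytoplankton-phytoplankton (`PP`) or bacteria-phytoplankton (`BP`) and
#' tabulates counts and fractions by pair type and sign — both as a fraction
#' of all retained edges and as a fraction within the edge's sign class.
#'
#' @param network A `cooccurrence_network` whose nodes carry kingdom labels.
#' @return A tibble with columns `pair_type`, `sign`, `n`, `frac_of_edges`,
#'   `frac_within_sign`. Networks with a single kingdom are flagged via the
#'   `single_kingdom` attribute.
#' @export
cross_kingdom_composition <- function(network) {
  stopifnot(inherits(network, "cooccurrence_network"))
  kingdom <- setNames(network$nodes$kingdom, network$nodes$taxon_id)
  if (any(is.na(kingdom))) {
    abort(paste0("node(s) without kingdom label: ",
                 paste(network$nodes$taxon_id[is.na(kingdom)], collapse = ", ")))
  }
  e <- network$edges
  pair_code <- function(a, b) {
    ka <- kingdom[a]; kb <- kingdom[b]
    ifelse(ka != kb, "BP", ifelse(ka == "bacteria", "BB", "PP"))
  }
  grid <- tidyr::expand_grid(pair_type = c("BB", "PP", "BP"), sign = c("+", "-"))
  if (nrow(e) == 0) {
    out <- dplyr::mutate(grid, n = 0L, frac_of_edges = NA_real_, frac_within_sign = NA_real_)
  } else {
    tab <- tibble::tibble(pair_type = pair_code(e$taxon_i, e$taxon_j), sign = e$sign) |>
      dplyr::count(.data$pair_type, .data$sign)
    out <- dplyr::left_join(grid, tab, by = c("pair_type", "sign")) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
      dplyr::group_by(.data$sign) |>
      dplyr::mutate(frac_within_sign = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_) |>
      dplyr::ungroup() |>
      dplyr::mutate(frac_of_edges = .data$n / nrow(e)) |>
      dplyr::select("pair_type", "sign", "n", "frac_of_edges", "frac_within_sign")
  }
  attr(out, "single_kingdom") <- length(unique(kingdom)) < 2
  attr(out, "group") <- network$group
  out
}

#' Compare topology metrics across trophic groups
#'
#' Given per-group topology rows in low-to-high trophic order, reports each
#' metric's first-to-last difference and a monotonicity flag: `"decreasing"`,
#' `"increasing"`, `"flat"` or `"non-monotonic"` (weak monotonicity with at
#' least one strict step).
#'
#' @param topologies A list of `network_topology` rows (or a data frame of
#'   them), ordered L, M, H.
#' @return A tibble with columns `metric`, one column per group, `delta`
#'   (last minus first) and `trend`.
#' @export
compare_topologies <- function(topologies) {
  if (inherits(topologies, "network_topology")) topologies <- list(topologies)
  df <- if (is.data.frame(topologies)) tibble::as_tibble(topologies) else dplyr::bind_rows(topologies)
  if (nrow(df) < 2) abort("need at least 2 groups to compare")
  groups <- if (all(is.na(df$group))) paste0("g", seq_len(nrow(df))) else as.character(df$group)
  metrics <- c("n_nodes", "n_edges", "avg_degree", "diameter", "clustering_coefficient",
               "modularity", "avg_path_length", "pct_positive_edges", "pct_negative_edges")
  purrr::map_dfr(metrics, function(mt) {
    v <- df[[mt]]
    row <- tibble::tibble(metric = mt)
    for (i in seq_along(groups)) row[[groups[i]]] <- v[i]
    row$delta <- v[length(v)] - v[1]
    row$trend <- trend_flag(v)
    row
  })
}

trend_flag <- function(v) {
  d <- diff(v)
  if (all(d == 0)) "flat"
  else if (all(d <= 0) && any(d < 0)) "decreasing"
  else if (all(d >= 0) && any(d > 0)) "increasing"
  else "non-monotonic"
}
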