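#' Relative abundance of taxa or phyla
#'
#' Converts a taxa-by-sample count table to per-sample proportions, optionally
#' aggregating member taxa to phylum first. Phytoplankton cell densities and
#' bacterial read counts live on incommensurable scales; the relative-abundance
#' transform is what makes them comparable, so kingdoms should be transformed
#' separately (see [build_network()], which does this per kingdom).
#'
#' @param counts Data frame, first column `taxon_id`, remaining columns numeric
#'   per-sample counts.
#' @param taxonomy Optional data frame with columns `taxon_id` and `phylum`;
#'   required when `level = "phylum"`.
#' @param level `"taxon"` (default) or `"phylum"`.
#' @return A tibble in the same layout whose sample columns each sum to 1.
#' @examples
#' counts <- tibble::tibble(taxon_id = c("t1", "t2"), s1 = c(2, 2))
#' relative_abundance(counts)
#' @export
relative_abundance <- function(counts, taxonomy = NULL, level = c("taxon", "phylum")) {
  level <- match.arg(level)
  m <- counts_matrix(counts)
  if (level == "phylum") {
    if (is.null(taxonomy)) abort("`taxonomy` is required for phylum-level aggregation")
    phyla <- setNames(as.character(taxonomy$phylum), as.character(taxonomy$taxon_id))
    unknown <- setdiff(rownames(m), names(phyla))
    if (length(unknown)) abort(paste0("taxa missing from taxonomy: ", paste(unknown, collapse = ", ")))
    m <- rowsum(m, group = phyla[rownames(m)])
  }
  totals <- colSums(m)
  zero <- totals <= 0
  if (any(zero)) {
    abort(paste0("sample(s) with zero total count: ", paste(colnames(m)[zero], collapse = ", ")))
  }
  out <- sweep(m, 2, totals, "/")
  id_col <- if (level == "phylum") "phylum" else "taxon_id"
  setNames(counts_tibble(out), c(id_col, colnames(out)))
}

#' Shannon diversity (natural-log entropy)
#'
#' `H = -sum(p_i * ln(p_i))` over the positive entries of a count vector,
#' with `p_i` the within-sample proportions. Zero counts contribute nothing.
#' `H` is 0 for a single-taxon community and at most `ln(S)` for richness `S`.
#'
#' @param x Non-negative numeric vector of counts (or proportions) with at
#'   least one positive entry.
#' @return Shannon entropy in nats.
#' @examples
#' shannon(c(5, 5, 5, 5))  # log(4)
#' @export
shannon <- function(x) {
  if (!is.numeric(x) || any(x < 0) || any(!is.finite(x))) abort("counts must be finite and non-negative")
  if (sum(x) <= 0) abort("all-zero count vector: Shannon diversity is undefined")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Taxon richness
#'
#' The number of strictly positive entries of a count vector (positivity, not
#' integrality, is what counts: densities qualify).
#'
#' @param x Non-negative numeric vector.
#' @return Integer count of taxa present.
#' @export
richness <- function(x) {
  if (!is.numeric(x) || any(x < 0)) abort("counts must be non-negative")
  sum(x > 0)
}

#' Per-sample diversity table
#'
#' Richness and Shannon entropy for every sample column of a count table.
#'
#' @inheritParams relative_abundance
#' @return A tibble with columns `sample_id`, `richness`, `shannon`.
#' @export
diversity_table <- function(counts) {
  m <- counts_matrix(counts)
  tibble::tibble(
    sample_id = colnames(m),
    richness = unname(apply(m, 2, richness)),
    shannon = unname(apply(m, 2, shannon))
  )
}

#' Rarefy read counts to a common depth
#'
#' Randomly subsamples each sample's reads without replacement down to `depth`
#' reads (the classic correction for library-size bias before alpha-diversity
#' comparison). Samples whose total falls below `depth` are dropped with a
#' warning rather than resampled — the conservative rule. Defined on read
#' counts only: non-integer counts are rejected.
#'
#' The draw is delegated to [vegan::rrarefy()] under a fixed seed, so results
#' are reproducible for a given `(counts, depth, seed)`.
#'
#' @inheritParams relative_abundance
#' @param depth Target reads per sample (default 27000).
#' @param seed Integer RNG seed.
#' @return A tibble in the count-table layout; every retained sample column
#'   sums to exactly `depth`. Dropped samples are recorded in the
#'   `dropped_samples` attribute.
#' @export
rarefy <- function(counts, depth = 27000, seed = 1) {
  m <- counts_matrix(counts)
  if (any(m != round(m))) abort("rarefaction is defined on integer read counts")
  if (depth < 1) abort("`depth` must be at least 1")
  totals <- colSums(m)
  drop <- totals < depth
  if (any(drop)) {
    warn(paste0("dropping sample(s) below rarefaction depth ", depth, ": ",
                paste(colnames(m)[drop], collapse = ", ")))
  }
  keep <- m[, !drop, drop = FALSE]
  if (ncol(keep) == 0) abort("no sample reaches the rarefaction depth")
  rar <- with_stage_seed(seed, "rarefy", withCallingHandlers(
    t(vegan::rrarefy(t(keep), sample = depth)),
    # vegan speculates about scaled data whenever the smallest count is
    # large; the integer check above already guarantees observed counts
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  ))
  out <- counts_tibble(rar)
  attr(out, "dropped_samples") <- colnames(m)[drop]
  attr(out, "depth") <- depth
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarity between sample columns:
#' `d(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`, in `[0, 1]`,
#' zero on the diagonal, symmetric. Computed via [vegan::vegdist()].
#'
#' @inheritParams relative_abundance
#' @param transform `"none"` (use counts as given) or `"relative"` (convert
#'   each sample to proportions first; appropriate for instrument-scaled cell
#'   densities). The choice is recorded in the `transform` attribute.
#' @return A labelled square numeric matrix of dissimilarities.
#' @export
bray_curtis <- function(counts, transform = c("none", "relative")) {
  transform <- match.arg(transform)
  m <- counts_matrix(counts)
  if (ncol(m) < 2) abort("Bray-Curtis needs at least two samples")
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(paste0("sample(s) with zero total count: ",
                 paste(colnames(m)[totals <= 0], collapse = ", ")))
  }
  if (transform == "relative") m <- sweep(m, 2, totals, "/")
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  attr(d, "transform") <- transform
  d
}
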