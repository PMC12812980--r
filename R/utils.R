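# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed for a named pipeline stage, so adding a
# stage never perturbs the draws of earlier stages.
derive_seed <- function(seed, stage) {
  h <- rlang::hash(list(as.integer(seed), as.character(stage)))
  # first 7 hex digits < 2^28, safely inside 32-bit integer range
  strtoi(substr(h, 1, 7), base = 16L)
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(derive_seed(seed, stage), code)
}

# Counts tables travel as data frames whose first column is taxon_id and whose
# remaining columns are numeric sample columns.  These two helpers convert
# between that interchange form and a taxa x samples numeric matrix.
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2)
  ids <- as.character(counts[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate taxon_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("count columns must be numeric")
  if (any(is.na(m))) abort("count table contains missing values")
  if (any(m < 0)) abort("count table contains negative values")
  rownames(m) <- ids
  m
}

counts_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "taxon_id")
}

# Rank-based statistics are sign-agnostic: this variant of the conversion
# enforces structure (unique ids, numeric, no NA) but not non-negativity.
numeric_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2)
  ids <- as.character(counts[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate taxon_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("data columns must be numeric")
  if (any(is.na(m))) abort("table contains missing values")
  rownames(m) <- ids
  m
}

# Symmetric zero-diagonal check used by the Mantel family.
check_distance_matrix <- function(d, arg = "d") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort(sprintf("%s must be square", arg))
  if (any(abs(d - t(d)) > 1e-12)) abort(sprintf("%s must be symmetric", arg))
  if (any(abs(diag(d)) > 1e-12)) abort(sprintf("%s must have a zero diagonal", arg))
  d
}

upper_tri_vec <- function(d) d[upper.tri(d)]

# Average ranks (ties.method = "average"), the rank transform behind every
# Spearman statistic in the package.
avg_rank <- function(x) rank(x, ties.method = "average")

`%||%` <- rlang::`%||%`
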