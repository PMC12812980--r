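#' Tie-aware Spearman rank correlation
#'
#' Pearson correlation of average-ranked values; tied observations receive the
#' average of the ranks they span. Spearman's invariance under strictly
#' monotone transforms is what makes phytoplankton cell densities and
#' bacterial read counts commensurable in the co-occurrence stage.
#'
#' @param x,y Equal-length numeric vectors, length >= 4.
#' @return The correlation in `[-1, 1]`, or `NA` (flagged by an attribute
#'   `undefined = TRUE`) if either vector is constant.
#' @examples
#' spearman_rho(1:5, (1:5)^2)  # 1: monotone transform invariance
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 4) abort("Spearman correlation needs at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cor(avg_rank(x), avg_rank(y))
}

# Two-sided p-value for a Spearman rho: t-distribution approximation for
# n >= 10, exact permutation enumeration below, where the approximation is
# unreliable and enumeration is cheap.
spearman_p <- function(rho, n, rx = NULL, ry = NULL) {
  if (is.na(rho)) return(NA_real_)
  if (n >= 10) {
    r2 <- min(rho^2, 1)
    if (r2 >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    2 * pt(-abs(tstat), df = n - 2)
  } else {
    stopifnot(!is.null(rx), !is.null(ry))
    perms <- all_permutations(n)
    crx <- rx - mean(rx)
    cry <- ry - mean(ry)
    denom <- sqrt(sum(crx^2)) * sqrt(sum(cry^2))
    permuted <- matrix(cry[perms], nrow = nrow(perms))
    rho_perm <- as.numeric(permuted %*% crx) / denom
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
}

# All n! permutations of 1:n as a matrix (n! rows); n is small (< 10).
# Cached per n: the enumeration is reused across the pairs of a matrix.
.perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- matrix(1L, 1, 1)
  if (n > 1) {
    for (k in 2:n) {
      p <- do.call(rbind, lapply(seq_len(k), function(pos) {
        cbind(p[, seq_len(pos - 1), drop = FALSE], k, p[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
      }))
    }
  }
  .perm_cache[[key]] <- p
  p
}

#' All-pairs Spearman correlation with FDR adjustment
#'
#' Computes the tie-aware Spearman correlation, its two-sided p-value and the
#' Benjamini-Hochberg q-value for every unordered pair of taxa (rows) of a
#' count table, across sample columns. The BH adjustment is applied once over
#' the full pair set. Constant taxa give `NA` correlations and are excluded
#' from the adjustment.
#'
#' @param counts Data frame, first column `taxon_id`, remaining columns the
#'   (at least 4) sample columns.
#' @return A tibble with columns `taxon_i`, `taxon_j`, `rho`, `p`, `q`,
#'   one row per unordered pair, `T*(T-1)/2` rows in total.
#' @export
correlation_matrix <- function(counts) {
  m <- numeric_matrix(counts)
  n <- ncol(m)
  if (n < 4) abort("correlation matrix needs at least 4 samples")
  if (nrow(m) < 2) abort("correlation matrix needs at least 2 taxa")
  ranks <- t(apply(m, 1, avg_rank))
  constant <- apply(m, 1, sd) == 0
  rho_mat <- suppressWarnings(cor(t(ranks)))
  rho_mat[constant, ] <- NA
  rho_mat[, constant] <- NA
  idx <- which(upper.tri(rho_mat), arr.ind = TRUE)
  rho <- rho_mat[upper.tri(rho_mat)]
  p <- if (n >= 10) {
    spearman_p_vec(rho, n)
  } else {
    vapply(seq_len(nrow(idx)), function(k) {
      spearman_p(rho[k], n, rx = ranks[idx[k, 1], ], ry = ranks[idx[k, 2], ])
    }, 1)
  }
  tibble::tibble(
    taxon_i = rownames(m)[idx[, 1]],
    taxon_j = rownames(m)[idx[, 2]],
    rho = rho,
    p = p,
    q = bh_fdr(p)
  )
}

# vectorised t-approximation (n >= 10)
spearman_p_vec <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- !is.na(rho)
  r2 <- pmin(rho[ok]^2, 1)
  tstat <- ifelse(r2 >= 1, Inf, rho[ok] * sqrt((n - 2) / (1 - r2)))
  p[ok] <- 2 * pt(-abs(tstat), df = n - 2)
  p
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted values: for sorted p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min over j >= i of m * p_(j) / j`, clipped to 1 and mapped back to
#' the input order. `NA` entries stay `NA` and do not count towards `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted q-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  o <- order(pv)
  qs <- rev(cummin(rev(m * pv[o] / seq_len(m))))
  qs <- pmin(qs, 1)
  q[ok][o] <- qs
  q
}

new_mantel_result <- function(r, p, n_perm, seed, method, statistic, undefined = FALSE) {
  structure(
    list(r = r, p = p, n_perm = n_perm, seed = seed, method = method,
         statistic = statistic, undefined = undefined),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat(sprintf("Mantel-type test (%s): undefined (constant input)\n", x$statistic))
  } else {
    cat(sprintf("Mantel-type test (%s, %s): r = %.4f, p = %.4g (%d permutations, one-tailed greater)\n",
                x$statistic, x$method, x$r, x$p, x$n_perm))
  }
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, method = x$method, r = x$r, p = x$p,
                 n_perm = x$n_perm, undefined = x$undefined)
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)

#' Mantel permutation test between two distance matrices
#'
#' Correlates the upper triangles of two conformable distance matrices
#' (Spearman by default, Pearson by option) and assesses significance by
#' jointly permuting the rows and columns of `d2`. The p-value uses the
#' add-one formula `p = (1 + #permuted r >= observed r) / (1 + n_perm)`,
#' one-tailed (greater), so its resolution is `1/(n_perm + 1)`. With
#' `exhaustive = TRUE` all `n!` relabelings are enumerated instead and
#' `p = #(r_perm >= r_obs) / n!` (the enumeration includes the identity).
#'
#' @param d1,d2 Square symmetric zero-diagonal matrices of equal dimension
#'   (at least 4).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer RNG seed; results are reproducible given
#'   `(d1, d2, n_perm, seed)`.
#' @param method `"spearman"` (default) or `"pearson"` correlation on the
#'   distance entries.
#' @param exhaustive Enumerate all permutations (small `n` only).
#' @return A `mantel_result`: list with elements `r`, `p`, `n_perm`, `seed`,
#'   `method`, `statistic`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1,
                        method = c("spearman", "pearson"), exhaustive = FALSE) {
  method <- match.arg(method)
  d1 <- check_distance_matrix(d1, "d1")
  d2 <- check_distance_matrix(d2, "d2")
  n <- nrow(d1)
  if (n != nrow(d2)) abort("`d1` and `d2` must have the same dimension")
  if (n < 4) abort("Mantel test needs at least 4 objects")
  v1 <- upper_tri_vec(d1)
  if (method == "spearman") {
    v1 <- avg_rank(v1)
    d2r <- rank_matrix(d2)
  } else {
    d2r <- d2
  }
  obs <- cor(v1, upper_tri_vec(d2r))
  perm_r <- mantel_permuted_r(function(dd) cor(v1, upper_tri_vec(dd)),
                              d2r, n, n_perm, seed, exhaustive)
  finish_mantel(obs, perm_r, exhaustive, n_perm, seed, method, "mantel")
}

# place upper-triangle ranks back into a symmetric matrix so that joint
# row/column permutation commutes with the rank transform
rank_matrix <- function(d) {
  r <- matrix(0, nrow(d), ncol(d))
  r[upper.tri(r)] <- avg_rank(upper_tri_vec(d))
  r + t(r)
}

mantel_permuted_r <- function(stat_fn, d2r, n, n_perm, seed, exhaustive) {
  if (exhaustive) {
    perms <- all_permutations(n)
    apply(perms, 1, function(idx) stat_fn(d2r[idx, idx]))
  } else {
    with_stage_seed(seed, "mantel", {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n)
        stat_fn(d2r[idx, idx])
      }, 1)
    })
  }
}

finish_mantel <- function(obs, perm_r, exhaustive, n_perm, seed, method, statistic) {
  if (exhaustive) {
    p <- mean(perm_r >= obs - 1e-12)
    n_used <- length(perm_r)
  } else {
    p <- (1 + sum(perm_r >= obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  new_mantel_result(r = obs, p = p, n_perm = n_used, seed = seed,
                    method = method, statistic = statistic)
}

#' Partial Mantel test
#'
#' Correlation between `d1` and `d2` upper triangles after linear removal of a
#' control distance matrix from both (residuals of least-squares fits on the
#' control's entries; ranks are taken first under the Spearman method).
#' Significance by joint row/column permutation of `d2`, as in [mantel_test()].
#'
#' @inheritParams mantel_test
#' @param d_control Square symmetric zero-diagonal control matrix.
#' @return A `mantel_result` with `statistic = "partial_mantel"`.
#' @export
partial_mantel <- function(d1, d2, d_control, n_perm = 999, seed = 1,
                           method = c("spearman", "pearson"), exhaustive = FALSE) {
  method <- match.arg(method)
  d1 <- check_distance_matrix(d1, "d1")
  d2 <- check_distance_matrix(d2, "d2")
  dc <- check_distance_matrix(d_control, "d_control")
  n <- nrow(d1)
  if (n != nrow(d2) || n != nrow(dc)) abort("all three matrices must have the same dimension")
  if (n < 4) abort("partial Mantel test needs at least 4 objects")
  transform <- if (method == "spearman") function(d) rank_matrix(d) else identity
  d1r <- transform(d1); d2r <- transform(d2); dcr <- transform(dc)
  vz <- upper_tri_vec(dcr)
  res_x <- lsq_residuals(upper_tri_vec(d1r), vz)
  stat_fn <- function(dd) {
    res_y <- lsq_residuals(upper_tri_vec(dd), vz)
    if (sd(res_x) == 0 || sd(res_y) == 0) return(0)
    cor(res_x, res_y)
  }
  obs <- stat_fn(d2r)
  perm_r <- mantel_permuted_r(stat_fn, d2r, n, n_perm, seed, exhaustive)
  finish_mantel(obs, perm_r, exhaustive, n_perm, seed, method, "partial_mantel")
}

lsq_residuals <- function(y, z) {
  if (sd(z) == 0) return(y - mean(y))
  fit <- stats::lm.fit(cbind(1, z), y)
  fit$residuals
}

#' Environment-community permutation correlation
#'
#' Distance-based stand-in for an envfit-style Monte Carlo test of a single
#' environmental variable against a community dissimilarity matrix: the
#' variable is standardized, converted to a Euclidean distance matrix and
#' tested against the community matrix with [mantel_test()]. This approximates
#' the vector-fitting Monte Carlo procedure; it is not the same coefficient.
#'
#' @param env Numeric vector, one value per sample, in the order of the
#'   distance matrix rows.
#' @param community_dist Square symmetric community dissimilarity matrix.
#' @inheritParams mantel_test
#' @return A `mantel_result` with `statistic = "env_community"`; a constant
#'   `env` yields `r = NA` with `undefined = TRUE`.
#' @export
env_community_correlation <- function(env, community_dist, n_perm = 999, seed = 1,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  community_dist <- check_distance_matrix(community_dist, "community_dist")
  if (length(env) != nrow(community_dist)) {
    abort("`env` length must match the distance matrix dimension")
  }
  if (sd(env) == 0) {
    return(new_mantel_result(NA_real_, NA_real_, n_perm, seed, method,
                             "env_community", undefined = TRUE))
  }
  d_env <- as.matrix(dist(as.numeric(scale(env))))
  out <- mantel_test(community_dist, d_env, n_perm = n_perm, seed = seed, method = method)
  out$statistic <- "env_community"
  out
}
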