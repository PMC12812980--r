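#' Trophic State Index component scores
#'
#' Computes one component of the modified Carlson Trophic State Index (TSI)
#' used for Chinese river assessment. Each component is a log-linear transform
#' `10 * (a + b * ln(value))` of a single water-quality measurement:
#'
#' * `chl_a` — chlorophyll-a in ug/L, `(a, b) = (2.5, 1.086)`
#' * `tn`    — total nitrogen in mg/L, `(a, b) = (5.453, 1.694)`
#' * `tp`    — total phosphorus in mg/L, `(a, b) = (9.436, 1.624)`
#' * `sd`    — Secchi disk depth in m, `(a, b) = (5.118, -1.94)`
#'
#' Natural logarithms throughout; the printed constants are only consistent
#' with ln. Units are enforced by convention, never converted.
#'
#' @param value Numeric vector of measurements, strictly positive, in the
#'   component's unit (see above).
#' @param kind One of `"chl_a"`, `"tn"`, `"tp"`, `"sd"`.
#' @param site_id Optional site labels used to make error messages traceable.
#' @return Numeric vector of dimensionless component scores.
#' @examples
#' tsi_component(1, "chl_a")   # 25
#' tsi_component(2.9, "tn")
#' @export
tsi_component <- function(value, kind = c("chl_a", "tn", "tp", "sd"), site_id = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(value)) abort("`value` must be numeric")
  bad <- !is.finite(value) | value <= 0
  if (any(bad)) {
    where <- if (!is.null(site_id)) paste0(" at site(s) ", paste(site_id[bad], collapse = ", ")) else ""
    abort(sprintf("non-positive %s value%s: TSI components are defined on positive measurements only", kind, where))
  }
  cf <- tsi_coefficients()[[kind]]
  10 * (cf[["a"]] + cf[["b"]] * log(value))
}

tsi_coefficients <- function() {
  list(
    chl_a = c(a = 2.5, b = 1.086),
    tn    = c(a = 5.453, b = 1.694),
    tp    = c(a = 9.436, b = 1.624),
    sd    = c(a = 5.118, b = -1.94)
  )
}

tsi_weights <- function() {
  c(chl_a = 0.326, tn = 0.219, tp = 0.230, sd = 0.225)
}

#' Composite Trophic State Index
#'
#' Weighted sum of the four component scores with weights
#' 0.326 (Chl-a), 0.219 (TN), 0.230 (TP), 0.225 (SD). The weights sum to 1, so
#' equal components return themselves. All four components are required; there
#' is no missing-component rule in the index definition. `renormalize = TRUE`
#' opts into reweighting over the components supplied (an extension, never the
#' default).
#'
#' @param tsi_chl,tsi_tn,tsi_tp,tsi_sd Component scores (vectors recycle to a
#'   common length). `NA` marks an absent component.
#' @param renormalize If `TRUE`, missing components are dropped and the
#'   remaining weights rescaled to sum to 1.
#' @return Numeric vector of composite scores.
#' @examples
#' composite_tsi(50, 50, 50, 50)  # 50
#' @export
composite_tsi <- function(tsi_chl, tsi_tn, tsi_tp, tsi_sd, renormalize = FALSE) {
  comp <- vctrs_recycle(tsi_chl, tsi_tn, tsi_tp, tsi_sd)
  w <- tsi_weights()
  m <- do.call(cbind, comp)
  if (!renormalize && any(is.na(m))) {
    abort("all four TSI components are required; use `renormalize = TRUE` to opt into reweighting")
  }
  if (renormalize) {
    wm <- matrix(w, nrow(m), 4, byrow = TRUE)
    wm[is.na(m)] <- 0
    if (any(rowSums(wm) == 0)) abort("at least one TSI component is required")
    wm <- wm / rowSums(wm)
    rowSums(wm * m, na.rm = TRUE)
  } else {
    as.numeric(m %*% w)
  }
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(vapply(xs, length, 1L))
  lapply(xs, rep_len, length.out = n)
}

#' Trophic state classification
#'
#' Maps a composite TSI score to the five-class scale used for river
#' assessment: oligotrophic (TSI < 30), mesotrophic (30 <= TSI <= 50),
#' slightly eutrophic (50 < TSI <= 60), moderately eutrophic (60 < TSI <= 70)
#' and hyper-eutrophic (TSI > 70). A site is "eutrophic" when TSI > 50.
#'
#' @param tsi Numeric vector of composite scores (finite).
#' @return A factor with levels `oligotrophic`, `mesotrophic`,
#'   `slightly_eutrophic`, `moderately_eutrophic`, `hyper_eutrophic`.
#' @examples
#' classify_trophic_state(c(29.9, 30, 55.5, 66, 71))
#' @export
classify_trophic_state <- function(tsi) {
  if (!is.numeric(tsi) || any(!is.finite(tsi))) abort("`tsi` must be finite numeric")
  cut(tsi,
    breaks = c(-Inf, 30, 50, 60, 70, Inf),
    labels = trophic_levels(),
    right = FALSE, include.lowest = TRUE
  ) -> out
  # cut() with right = FALSE puts exactly 30 in the mesotrophic bin but also
  # puts exactly 50 in the next bin; the printed intervals are
  # [30, 50], (50, 60], (60, 70], so fix the three closed upper bounds.
  out[tsi == 50] <- "mesotrophic"
  out[tsi == 60] <- "slightly_eutrophic"
  out[tsi == 70] <- "moderately_eutrophic"
  out
}

trophic_levels <- function() {
  c("oligotrophic", "mesotrophic", "slightly_eutrophic", "moderately_eutrophic", "hyper_eutrophic")
}

#' Is a composite TSI eutrophic?
#'
#' The eutrophic predicate is `tsi > 50`, i.e. the union of the slightly,
#' moderately and hyper-eutrophic classes.
#'
#' @param tsi Numeric vector of composite scores.
#' @return Logical vector.
#' @export
is_eutrophic <- function(tsi) tsi > 50

#' Assess the trophic state of survey sites
#'
#' Computes, for each row of a water-chemistry table, the four TSI component
#' scores, the weighted composite TSI and the trophic class label. This is the
#' data-frame-first entry point of the trophic-state stage: pipe a chemistry
#' table in, get a per-site assessment tibble back. Summary statistics over the
#' cohort are available through [glance()] or [trophic_summary()].
#'
#' @param chemistry A data frame with columns `site_id`, `tn` (mg/L),
#'   `tp` (mg/L), `chl_a` (ug/L), `secchi` (m); extra columns are carried
#'   through untouched.
#' @return A tibble of class `trophic_assessment` with columns `site_id`,
#'   `tsi_chl`, `tsi_tn`, `tsi_tp`, `tsi_sd`, `tsi`, `label`, `eutrophic`.
#' @examples
#' chem <- tibble::tibble(site_id = c("a", "b"), tn = c(2.9, 1.2),
#'                        tp = c(0.09, 0.02), chl_a = c(6.3, 1.1),
#'                        secchi = c(0.79, 2.5))
#' assess_sites(chem)
#' @export
assess_sites <- function(chemistry) {
  required <- c("site_id", "tn", "tp", "chl_a", "secchi")
  missing_cols <- setdiff(required, names(chemistry))
  if (length(missing_cols)) {
    abort(paste0("chemistry table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(chemistry) == 0) abort("chemistry table is empty")
  ids <- as.character(chemistry$site_id)
  if (any(!nzchar(ids)) || anyDuplicated(ids)) {
    abort("site_id must be non-empty and unique")
  }
  for (col in c("tn", "tp", "chl_a", "secchi")) {
    v <- chemistry[[col]]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      abort(sprintf("invalid %s (non-positive or missing) at site(s): %s",
                    col, paste(ids[bad], collapse = ", ")))
    }
  }
  out <- tibble::tibble(
    site_id = ids,
    tsi_chl = tsi_component(chemistry$chl_a, "chl_a", ids),
    tsi_tn  = tsi_component(chemistry$tn, "tn", ids),
    tsi_tp  = tsi_component(chemistry$tp, "tp", ids),
    tsi_sd  = tsi_component(chemistry$secchi, "sd", ids)
  )
  out$tsi <- composite_tsi(out$tsi_chl, out$tsi_tn, out$tsi_tp, out$tsi_sd)
  out$label <- classify_trophic_state(out$tsi)
  out$eutrophic <- is_eutrophic(out$tsi)
  class(out) <- c("trophic_assessment", class(out))
  out
}

#' Cohort-level trophic summary
#'
#' One-row summary of a per-site assessment: class counts, the percentage of
#' eutrophic units (composite TSI > 50), and min / max / median / mean / sample
#' standard deviation of the composite TSI. One row of the assessment is one
#' classified unit. For a single unit the standard deviation is undefined and
#' reported as 0 with `sd_defined = FALSE`.
#'
#' @param assessment A `trophic_assessment` tibble from [assess_sites()].
#' @return A one-row tibble with columns `n_samples`, `n_oligotrophic`,
#'   `n_mesotrophic`, `n_slightly_eutrophic`, `n_moderately_eutrophic`,
#'   `n_hyper_eutrophic`, `pct_eutrophic`, `tsi_min`, `tsi_max`, `tsi_median`,
#'   `tsi_mean`, `tsi_sd`, `sd_defined`.
#' @export
trophic_summary <- function(assessment) {
  stopifnot(is.data.frame(assessment), all(c("tsi", "label") %in% names(assessment)))
  tsi <- assessment$tsi
  n <- length(tsi)
  counts <- table(factor(assessment$label, levels = trophic_levels()))
  tibble::tibble(
    n_samples = n,
    n_oligotrophic = as.integer(counts[["oligotrophic"]]),
    n_mesotrophic = as.integer(counts[["mesotrophic"]]),
    n_slightly_eutrophic = as.integer(counts[["slightly_eutrophic"]]),
    n_moderately_eutrophic = as.integer(counts[["moderately_eutrophic"]]),
    n_hyper_eutrophic = as.integer(counts[["hyper_eutrophic"]]),
    pct_eutrophic = 100 * mean(is_eutrophic(tsi)),
    tsi_min = min(tsi),
    tsi_max = max(tsi),
    tsi_median = median(tsi),
    tsi_mean = mean(tsi),
    tsi_sd = if (n > 1) sd(tsi) else 0,
    sd_defined = n > 1
  )
}

#' @export
glance.trophic_assessment <- function(x, ...) trophic_summary(x)

#' @export
tidy.trophic_assessment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "trophic_assessment")
  out
}

#' @export
print.trophic_assessment <- function(x, ...) {
  cat(sprintf("# Trophic assessment of %d unit(s); %.1f%% eutrophic\n",
              nrow(x), 100 * mean(x$eutrophic)))
  NextMethod()
}
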