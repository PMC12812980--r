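small_scenario <- function(...) {
  gradient_scenario(n_sites_per_group = c(L = 8, M = 8, H = 8), ...)
}

test_that("identical scenario and seed yield byte-identical datasets", {
  d1 <- simulate_dataset(small_scenario(), seed = 5)
  d2 <- simulate_dataset(small_scenario(), seed = 5)
  expect_identical(d1$chemistry, d2$chemistry)
  expect_identical(d1$phyto, d2$phyto)
  expect_identical(d1$bacteria, d2$bacteria)
  expect_identical(d1$truth$planted_edges, d2$truth$planted_edges)
  d3 <- simulate_dataset(small_scenario(), seed = 6)
  expect_false(identical(d1$bacteria, d3$bacteria))
})

test_that("zero-noise chemistry inverts the component formulas exactly", {
  scn <- small_scenario(chemistry_noise_sd = 0)
  gen <- generate_chemistry(scn, seed = 3)
  a <- assess_sites(gen$chemistry)
  expect_equal(a$tsi, gen$truth$target_tsi, tolerance = 1e-9)
  expect_equal(as.character(a$label), gen$truth$true_label)
  # closed-form inversion: a site targeted at exactly TSI 55 has
  # tn = exp((5.5 - 5.453)/1.694)
  scn55 <- gradient_scenario(n_sites_per_group = c(M = 4),
                             target_tsi_ranges = list(M = c(55, 55)),
                             chemistry_noise_sd = 0)
  g55 <- generate_chemistry(scn55, seed = 1)
  expect_equal(g55$chemistry$tn, rep(exp((5.5 - 5.453) / 1.694), 4), tolerance = 1e-12)
  expect_equal(g55$chemistry$tn[1], 1.028, tolerance = 1e-3)
  expect_equal(assess_sites(g55$chemistry)$tsi, rep(55, 4), tolerance = 1e-9)
})

test_that("moderate chemistry noise keeps class accuracy high", {
  scn <- gradient_scenario(n_sites_per_group = c(L = 34, M = 33, H = 33),
                           chemistry_noise_sd = 0.05)
  acc <- vapply(1:10, function(s) {
    gen <- generate_chemistry(scn, seed = s)
    mean(as.character(assess_sites(gen$chemistry)$label) == gen$truth$true_label)
  }, 1)
  expect_gte(mean(acc), 0.95)
})

test_that("excessive noise triggers the class-scramble warning with a confusion matrix", {
  scn <- small_scenario(chemistry_noise_sd = 1.5)
  expect_warning(generate_chemistry(scn, seed = 2), "scrambles")
})

test_that("communities carry the planted dominance patterns", {
  d <- simulate_dataset(gradient_scenario(n_sites_per_group = c(L = 30, M = 30, H = 30)), seed = 9)
  tax <- d$taxonomy
  m <- as.matrix(d$phyto[, -1]); rownames(m) <- d$phyto$taxon_id
  rel <- sweep(m, 2, colSums(m), "/")
  phy_frac <- function(ph, samples) {
    mean(colSums(rel[tax$phylum[match(rownames(rel), tax$taxon_id)] == ph, samples]))
  }
  L <- d$groups$sample_id[d$groups$group == "L"]
  H <- d$groups$sample_id[d$groups$group == "H"]
  expect_gt(phy_frac("Bacillariophyta", L), phy_frac("Cyanophyta", L))
  expect_gt(phy_frac("Cyanophyta", H), phy_frac("Bacillariophyta", H))
  # bacterial profiles are Proteobacteria-dominated near the planted baseline
  mb <- as.matrix(d$bacteria[, -1]); rownames(mb) <- d$bacteria$taxon_id
  relb <- sweep(mb, 2, colSums(mb), "/")
  proteo <- mean(colSums(relb[tax$phylum[match(rownames(relb), tax$taxon_id)] == "Proteobacteria", ]))
  expect_equal(proteo, 0.6, tolerance = 0.05)
  # diversity declines along the gradient
  div <- diversity_table(d$bacteria)
  sh <- tapply(div$shannon, d$groups$group[match(div$sample_id, d$groups$sample_id)], mean)
  expect_gt(sh[["L"]], sh[["M"]])
  expect_gt(sh[["M"]], sh[["H"]])
})

test_that("with no planted correlation the communities are rank-independent", {
  scn <- gradient_scenario(n_sites_per_group = c(L = 25, M = 25, H = 25),
                           module_spec = list(blocks = list(), cross = list()))
  d <- simulate_dataset(scn, seed = 13)
  expect_equal(nrow(d$truth$planted_edges), 0)
  L <- d$groups$sample_id[d$groups$group == "L"]
  mb <- as.matrix(d$bacteria[, L])
  rho <- cor(t(apply(mb, 1, rank)))
  off <- abs(rho[upper.tri(rho)])
  expect_lte(mean(off), 2 / sqrt(length(L)))
})

test_that("planted truth includes implied factor-sharing correlations", {
  d <- simulate_dataset(small_scenario(), seed = 1)
  pe <- d$truth$planted_edges
  blk <- setNames(d$truth$blocks$block, d$truth$blocks$taxon_id)
  # H couples B1 and B2 to the same diatom factor: B1-B2 pairs must be
  # planted with a positive implied correlation
  hh <- pe[pe$group == "H", ]
  b1b2 <- hh[!is.na(blk[hh$taxon_i]) & !is.na(blk[hh$taxon_j]) &
               blk[hh$taxon_i] == "B1" & blk[hh$taxon_j] == "B2", ]
  expect_equal(nrow(b1b2), 36)
  expect_true(all(b1b2$sign == "+"))
  expect_equal(unique(b1b2$latent_r), 0.94 * 0.92, tolerance = 1e-9)
  # no antagonistic coupling is planted in L
  expect_equal(sum(pe$sign[pe$group == "L"] == "-"), 0)
})

test_that("recovery scoring is exact on a zero-noise cohort", {
  scn <- small_scenario(chemistry_noise_sd = 0)
  d <- simulate_dataset(scn, seed = 21)
  a <- suppressWarnings(analyze_dataset(d, seed = 21))
  r <- score_recovery(a, d)
  expect_equal(r$class_accuracy, 1)
  expect_named(r$trends, c("shannon_decreasing", "modularity_decreasing",
                           "pct_negative_increasing"))
  expect_true(all(c("recall", "precision", "spurious_rate") %in% names(r$edges)))
  # identifiers must match between outputs and truth
  d2 <- d
  d2$truth$sites$site_id <- paste0("x", d2$truth$sites$site_id)
  expect_error(score_recovery(a, d2), "different site sets")
})

test_that("scenario invariants are enforced", {
  expect_error(gradient_scenario(proteobacteria_base_fraction = 1.2), "\\(0, 1\\)")
  expect_error(gradient_scenario(minor_phyto_fraction = 1), "\\[0, 1\\)")
  # coupling strengths beyond the within_r budget are rejected
  ms <- default_module_spec()
  ms$cross$H[[2]]$strength <- 0.99
  scn <- small_scenario(module_spec = ms)
  expect_error(simulate_dataset(scn, seed = 1), "budget")
})
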