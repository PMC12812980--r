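#' Define a synthetic eutrophication-gradient scenario
#'
#' A scenario bundles every free parameter of the synthetic data generator:
#' cohort sizes per trophic group, the target composite-TSI ranges the
#' chemistry is back-solved from, measurement noise, community sizes, the
#' diatom-to-cyanobacteria dominance turnover, the Proteobacteria-dominated
#' bacterial baseline with diversity declining along the gradient, the planted
#' signed correlation block structure, and sequencing library size.
#'
#' The defaults emulate the qualitative structure of a eutrophic river survey:
#' three trophic groups (L mesotrophic, M slightly eutrophic, H moderately
#' eutrophic), a logistic diatom-to-cyanobacteria shift centred at TSI 55,
#' bacterial profiles 60% Proteobacteria whose within-phylum evenness decays
#' with TSI (driving Shannon down), and four positively-correlated taxon
#' blocks (two per kingdom) with cross-kingdom *negative* coupling that is
#' absent in L and strengthens from M to H — so that negative-edge percentage
#' rises and modularity falls along the gradient, the pattern the network
#' stage is designed to detect.
#'
#' @param n_sites_per_group Named integer vector, sites per group (default 30
#'   each for L, M, H).
#' @param target_tsi_ranges Named list of length-2 numeric ranges the target
#'   composite TSI of each group is drawn from (defaults: L `[30, 50]`,
#'   M `(50, 60]`, H `(60, 70]`).
#' @param chemistry_noise_sd Standard deviation of the multiplicative
#'   lognormal jitter applied to back-solved chemistry (default 0.05).
#' @param n_phyto_taxa,n_bact_taxa Community sizes (defaults 33 and 40).
#' @param diatom_to_cyano_slope Logistic slope (per TSI unit) of the dominance
#'   turnover (default 0.15).
#' @param turnover_midpoint TSI at which diatoms and cyanobacteria trade
#'   dominance (default 55).
#' @param minor_phyto_fraction Total relative abundance held by the four minor
#'   phytoplankton phyla (default 0.3).
#' @param proteobacteria_base_fraction Proteobacteria share of each bacterial
#'   sample in expectation (default 0.6).
#' @param shannon_decline_rate Increase, per TSI unit, of the within-phylum
#'   power-law exponent of bacterial abundance ranks; larger means steeper
#'   diversity loss along the gradient (default 0.025). The Proteobacteria
#'   share also swells with TSI around its baseline, the second driver of
#'   the planted diversity decline.
#' @param module_spec Planted correlation structure: a list with `blocks` (a
#'   list of `list(name, kingdom, size, within_r)`) and `cross` (per group, a
#'   list of `list(from, to, strength)` couplings; `strength` is the loading
#'   of the `to` block on the `from` block's latent factor, with negative
#'   sign, so the planted cross-kingdom latent correlation is
#'   `-sqrt(within_r) * strength`). `NULL` plants no correlation at all.
#' @param library_size Expected reads per bacterial sample (default 30000).
#' @param nb_dispersion Negative-binomial size parameter of bacterial counts
#'   (default 10).
#' @param phyto_total Expected phytoplankton counting units per sample
#'   (default 10000).
#' @param phyto_dispersion Negative-binomial size parameter of phytoplankton
#'   counts (default 5).
#' @return A `gradient_scenario` list.
#' @export
gradient_scenario <- function(n_sites_per_group = c(L = 30, M = 30, H = 30),
                              target_tsi_ranges = list(L = c(30, 50), M = c(50, 60), H = c(60, 70)),
                              chemistry_noise_sd = 0.05,
                              n_phyto_taxa = 33,
                              n_bact_taxa = 40,
                              diatom_to_cyano_slope = 0.15,
                              turnover_midpoint = 55,
                              minor_phyto_fraction = 0.3,
                              proteobacteria_base_fraction = 0.6,
                              shannon_decline_rate = 0.025,
                              module_spec = default_module_spec(),
                              library_size = 30000,
                              nb_dispersion = 10,
                              phyto_total = 10000,
                              phyto_dispersion = 5) {
  groups <- names(n_sites_per_group)
  stopifnot(!is.null(groups), identical(sort(groups), sort(names(target_tsi_ranges))))
  if (minor_phyto_fraction < 0 || minor_phyto_fraction >= 1) abort("minor_phyto_fraction must be in [0, 1)")
  if (proteobacteria_base_fraction <= 0 || proteobacteria_base_fraction >= 1) {
    abort("proteobacteria_base_fraction must be in (0, 1)")
  }
  scenario <- list(
    n_sites_per_group = n_sites_per_group,
    target_tsi_ranges = target_tsi_ranges,
    chemistry_noise_sd = chemistry_noise_sd,
    n_phyto_taxa = n_phyto_taxa,
    n_bact_taxa = n_bact_taxa,
    diatom_to_cyano_slope = diatom_to_cyano_slope,
    turnover_midpoint = turnover_midpoint,
    minor_phyto_fraction = minor_phyto_fraction,
    proteobacteria_base_fraction = proteobacteria_base_fraction,
    shannon_decline_rate = shannon_decline_rate,
    module_spec = module_spec %||% list(blocks = list(), cross = list()),
    library_size = library_size,
    nb_dispersion = nb_dispersion,
    phyto_total = phyto_total,
    phyto_dispersion = phyto_dispersion
  )
  structure(scenario, class = "gradient_scenario")
}

#' Default planted correlation block structure
#'
#' Six positively-correlated blocks (within-block latent correlation 0.9):
#' P1 (6 diatom taxa), P2 (6 cyanobacterial phytoplankton), P3 (3 green
#' algae), B1 (6 Proteobacteria), B2 (6 Bacteroidota) and B3
#' (3 Actinobacteria). Blocks are coupled across kingdoms through shared
#' latent factors, and the coupling pattern is what changes along the
#' gradient:
#'
#' * a mutualistic module P3-B3 is coupled *positively* in every group, with
#'   strength fading from L (0.92) through M (0.82) to H (0.72) — so the share
#'   of positive cross-kingdom edges declines as trophic state rises;
#' * antagonistic couplings appear and densify with trophic state: none in
#'   L, B1 against the diatom factor in M (0.88), and in H both B1 (0.94)
#'   and B2 (0.92) against the diatom factor — which also implies a positive
#'   B1-B2 association (0.86) — so negative-edge percentage rises and the
#'   module boundaries collapse into one dominant mixed module (modularity
#'   falls sharply) from L to H.
#'
#' @return A `module_spec` list (see [gradient_scenario()]).
#' @export
default_module_spec <- function() {
  list(
    blocks = list(
      list(name = "P1", kingdom = "phytoplankton", size = 6, within_r = 0.9),
      list(name = "P2", kingdom = "phytoplankton", size = 6, within_r = 0.9),
      list(name = "P3", kingdom = "phytoplankton", size = 3, within_r = 0.9),
      list(name = "B1", kingdom = "bacteria", size = 6, within_r = 0.9),
      list(name = "B2", kingdom = "bacteria", size = 6, within_r = 0.9),
      list(name = "B3", kingdom = "bacteria", size = 3, within_r = 0.9)
    ),
    cross = list(
      L = list(
        list(from = "P3", to = "B3", strength = 0.92, sign = "+")
      ),
      M = list(
        list(from = "P3", to = "B3", strength = 0.82, sign = "+"),
        list(from = "P1", to = "B1", strength = 0.88, sign = "-")
      ),
      H = list(
        list(from = "P3", to = "B3", strength = 0.72, sign = "+"),
        list(from = "P1", to = "B1", strength = 0.94, sign = "-"),
        list(from = "P1", to = "B2", strength = 0.92, sign = "-")
      )
    )
  )
}

# ---- taxonomy ---------------------------------------------------------------

phyto_phyla <- function() {
  c("Bacillariophyta", "Cyanophyta", "Chlorophyta", "Cryptophyta", "Pyrrophyta", "Euglenophyta")
}

bact_phyla <- function() {
  c("Proteobacteria", "Actinobacteria", "Bacteroidota", "Cyanobacteria", "Firmicutes", "Verrucomicrobia")
}

# Deterministic taxonomy. Host phyla: P1 in Bacillariophyta, P2 in
# Cyanophyta, P3 in Chlorophyta; B1 in Proteobacteria, B2 in Bacteroidota,
# B3 in Actinobacteria. Block members sit at the *tail* abundance ranks of
# their host phylum so that no block carries a dominant share of its
# kingdom total: the relative-abundance transform closes each kingdom to 1,
# and a dominant co-varying block would see its shared signal partially
# cancelled by its own contribution to the denominator.
build_taxonomy <- function(scenario) {
  ms <- scenario$module_spec
  block_of <- function(kingdom) Filter(function(b) b$kingdom == kingdom, ms$blocks)
  pb <- block_of("phytoplankton")
  bb <- block_of("bacteria")
  n_p <- scenario$n_phyto_taxa
  n_b <- scenario$n_bact_taxa
  sz <- function(blocks, i) if (length(blocks) >= i) blocks[[i]]$size else 0

  # phytoplankton: host phyla padded with non-block taxa ahead of the blocks
  p_ids <- sprintf("p%02d", seq_len(n_p))
  n_diatom <- sz(pb, 1) + 5
  n_cyano <- sz(pb, 2) + 5
  n_chloro <- sz(pb, 3) + 2
  n_minor <- n_p - n_diatom - n_cyano - n_chloro
  if (n_minor < 0) abort("n_phyto_taxa too small for the phytoplankton blocks")
  minor <- rep_len(phyto_phyla()[4:6], n_minor)
  p_phyla <- c(rep("Bacillariophyta", n_diatom), rep("Cyanophyta", n_cyano),
               rep("Chlorophyta", n_chloro), sort(minor))

  # bacteria: Proteobacteria dominated, blocks spread over three phyla
  b_ids <- sprintf("b%02d", seq_len(n_b))
  n_proteo <- sz(bb, 1) + 9
  n_bactero <- sz(bb, 2) + 2
  n_actino <- sz(bb, 3) + 3
  n_rest <- n_b - n_proteo - n_bactero - n_actino
  if (n_rest < 0) abort("n_bact_taxa too small for the bacterial blocks")
  rest <- rep_len(bact_phyla()[4:6], n_rest)
  b_phyla <- c(rep("Proteobacteria", n_proteo), rep("Bacteroidota", n_bactero),
               rep("Actinobacteria", n_actino), sort(rest))

  taxonomy <- tibble::tibble(
    taxon_id = c(p_ids, b_ids),
    kingdom = c(rep("phytoplankton", n_p), rep("bacteria", n_b)),
    phylum = c(p_phyla, b_phyla),
    genus = paste0("genus_", c(p_ids, b_ids))
  )

  # block membership: the last `size` abundance ranks of the host phylum
  membership <- setNames(rep(NA_character_, n_p + n_b), taxonomy$taxon_id)
  assign_block <- function(membership, block, host_ids) {
    free <- host_ids[is.na(membership[host_ids])]
    if (length(free) < block$size) abort(sprintf("host phylum too small for block %s", block$name))
    membership[utils::tail(free, block$size)] <- block$name
    membership
  }
  phyto_hosts <- list(p_ids[p_phyla == "Bacillariophyta"],
                      p_ids[p_phyla == "Cyanophyta"],
                      p_ids[p_phyla == "Chlorophyta"])
  bact_hosts <- list(b_ids[b_phyla == "Proteobacteria"],
                     b_ids[b_phyla == "Bacteroidota"],
                     b_ids[b_phyla == "Actinobacteria"])
  for (i in seq_along(pb)) {
    membership <- assign_block(membership, pb[[i]], phyto_hosts[[min(i, 3)]])
  }
  for (i in seq_along(bb)) {
    membership <- assign_block(membership, bb[[i]], bact_hosts[[min(i, 3)]])
  }
  taxonomy$block <- unname(membership[taxonomy$taxon_id])
  taxonomy
}

# ---- chemistry --------------------------------------------------------------

#' Generate synthetic water chemistry along a trophic gradient
#'
#' For each site a target composite TSI is drawn uniformly within its group's
#' range; every component measurement is then back-solved from the target by
#' inverting its component formula (`value = exp((TSI/10 - a) / b)`) and
#' jittered by multiplicative lognormal noise. At zero noise the recomputed
#' composite TSI equals the target exactly, so every site's class is known by
#' construction. If noise scrambles more than 10% of classes a warning with
#' the realized confusion matrix is emitted.
#'
#' @param scenario A [gradient_scenario()].
#' @param seed Integer seed; the draw is reproducible given
#'   `(scenario, seed)`.
#' @return A list with `chemistry` (tibble: `site_id`, `tn`, `tp`, `chl_a`,
#'   `secchi`, plus covariates `wt`, `do`, `cod`) and `truth` (tibble:
#'   `site_id`, `group`, `target_tsi`, `true_label`).
#' @export
generate_chemistry <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "gradient_scenario"))
  groups <- names(scenario$n_sites_per_group)
  with_stage_seed(seed, "chemistry", {
    truth <- purrr::map_dfr(groups, function(g) {
      n <- scenario$n_sites_per_group[[g]]
      rng <- scenario$target_tsi_ranges[[g]]
      tibble::tibble(
        site_id = sprintf("%s%02d", g, seq_len(n)),
        group = g,
        target_tsi = runif(n, rng[1], rng[2])
      )
    })
    truth$true_label <- as.character(classify_trophic_state(truth$target_tsi))
    cf <- tsi_coefficients()
    backsolve <- function(target, kind) exp((target / 10 - cf[[kind]][["a"]]) / cf[[kind]][["b"]])
    n <- nrow(truth)
    jitter <- function() exp(rnorm(n, 0, scenario$chemistry_noise_sd))
    chemistry <- tibble::tibble(
      site_id = truth$site_id,
      tn = backsolve(truth$target_tsi, "tn") * jitter(),
      tp = backsolve(truth$target_tsi, "tp") * jitter(),
      chl_a = backsolve(truth$target_tsi, "chl_a") * jitter(),
      secchi = backsolve(truth$target_tsi, "sd") * jitter(),
      wt = 20 + 0.10 * (truth$target_tsi - 50) + rnorm(n, 0, 1),
      do = 9 - 0.05 * (truth$target_tsi - 50) + rnorm(n, 0, 0.5),
      cod = exp(log(3) + 0.02 * (truth$target_tsi - 50) + rnorm(n, 0, 0.1))
    )
    realized <- assess_sites(chemistry)
    acc <- mean(as.character(realized$label) == truth$true_label)
    if (acc < 0.8) {
      cm <- table(truth = truth$true_label, realized = as.character(realized$label))
      warn(paste0("chemistry noise scrambles trophic classes (accuracy ", round(acc, 3), "):\n",
                  paste(utils::capture.output(print(cm)), collapse = "\n")))
    }
    list(chemistry = chemistry, truth = truth)
  })
}

# ---- communities ------------------------------------------------------------

# Per-site expected relative abundance of every taxon, plus the dominance
# fractions that constitute planted truth.  Composition responds to the
# trophic gradient at the group level: every site uses the
# representative TSI of its group (the midpoint of the target range), so
# within-group covariation is carried exclusively by the planted copula and
# counting noise, never by shared mean trends.
expected_profiles <- function(scenario, taxonomy, groups) {
  rep_tsi <- vapply(scenario$target_tsi_ranges, mean, 1)
  comp_tsi <- rep_tsi[groups]
  n_sites <- length(comp_tsi)
  phy <- taxonomy[taxonomy$kingdom == "phytoplankton", ]
  bac <- taxonomy[taxonomy$kingdom == "bacteria", ]

  # phytoplankton phylum weights: logistic diatom -> cyanobacteria turnover
  f_cyano <- stats::plogis(scenario$diatom_to_cyano_slope * (comp_tsi - scenario$turnover_midpoint))
  major <- 1 - scenario$minor_phyto_fraction
  minor_phyla <- setdiff(unique(phy$phylum), c("Bacillariophyta", "Cyanophyta"))
  w_phy <- sapply(unique(phy$phylum), function(ph) {
    switch(ph,
      Bacillariophyta = major * (1 - f_cyano),
      Cyanophyta = major * f_cyano,
      rep(scenario$minor_phyto_fraction / max(length(minor_phyla), 1), n_sites)
    )
  })  # n_sites x phyla
  # within-phylum profile: fixed mild power law over rank
  p_prof <- matrix(0, nrow(phy), n_sites, dimnames = list(phy$taxon_id, NULL))
  for (ph in unique(phy$phylum)) {
    members <- phy$taxon_id[phy$phylum == ph]
    z <- seq_along(members)^(-1)
    z <- z / sum(z)
    p_prof[members, ] <- z %o% w_phy[, ph]
  }

  # bacteria: diversity declines along the gradient through two coupled
  # mechanisms — the Proteobacteria share swells around its baseline
  # (base - 0.15 at the L midpoint up to base + 0.10 at the H midpoint, so
  # the across-site mean sits at the baseline) and the within-phylum
  # power-law exponent grows with TSI (evenness loss). Keeping the exponent
  # moderate avoids concentrating the library in one or two taxa, whose
  # counting noise would otherwise dominate the relative-abundance
  # denominator shared by every taxon of the kingdom.
  w_proteo <- pmin(pmax(scenario$proteobacteria_base_fraction + 0.01 * (comp_tsi - 55), 0.05), 0.95)
  other <- c(Actinobacteria = 0.12, Bacteroidota = 0.12, Cyanobacteria = 0.08,
             Firmicutes = 0.04, Verrucomicrobia = 0.04)
  other <- other / sum(other)
  gamma_s <- pmax(0.4 + scenario$shannon_decline_rate * (comp_tsi - 40), 0.05)
  b_prof <- matrix(0, nrow(bac), n_sites, dimnames = list(bac$taxon_id, NULL))
  for (ph in unique(bac$phylum)) {
    members <- bac$taxon_id[bac$phylum == ph]
    w <- if (ph == "Proteobacteria") w_proteo else unname(other[ph]) * (1 - w_proteo)
    ranks <- seq_along(members)
    zipf <- outer(ranks, gamma_s, function(r, g) r^(-g))   # members x sites
    zipf <- sweep(zipf, 2, colSums(zipf), "/")
    b_prof[members, ] <- sweep(zipf, 2, w, "*")
  }
  b_prof <- sweep(b_prof, 2, colSums(b_prof), "/")

  list(
    phyto = p_prof, bact = b_prof,
    dominance = tibble::tibble(
      diatom_frac = major * (1 - f_cyano),
      cyano_frac = major * f_cyano,
      proteo_frac = w_proteo
    )
  )
}

# Factor-loading matrix of the planted correlation structure for one group:
# a taxa x factors matrix L plus per-taxon residual sd, so that the latent
# scores are z = L f + resid * eps with independent standard-normal factors
# f and noise eps. Every block has one factor; uncoupled block members load
# sqrt(within_r) on it; a block coupled to factors of other blocks splits its
# within_r budget between its own factor and the (signed) cross loadings, so
# within-block correlation stays within_r while cross-block correlation is
# sign * strength * sqrt(within_r_from). Couplings to a shared factor also
# imply secondary correlations (product of loadings); all implied pairs are
# emitted as planted truth.
block_loadings <- function(scenario, taxonomy, group) {
  ms <- scenario$module_spec
  taxa <- taxonomy$taxon_id
  n_blocks <- length(ms$blocks)
  loadings <- matrix(0, length(taxa), max(n_blocks, 1),
                     dimnames = list(taxa, if (n_blocks) vapply(ms$blocks, function(b) b$name, "") else "none"))
  resid <- setNames(rep(1, length(taxa)), taxa)
  if (!n_blocks) return(list(loadings = loadings, resid = resid))
  blocks <- setNames(ms$blocks, colnames(loadings))
  cross <- ms$cross[[group]] %||% list()
  for (b in blocks) {
    members <- taxa[!is.na(taxonomy$block) & taxonomy$block == b$name]
    ccs <- Filter(function(cc) cc$to == b$name, cross)
    budget <- b$within_r - sum(vapply(ccs, function(cc) cc$strength^2, 1))
    if (budget < 0) abort(sprintf("cross-coupling strengths of block %s exceed its within_r budget", b$name))
    loadings[members, b$name] <- sqrt(budget)
    for (cc in ccs) {
      sgn <- if (identical(cc$sign, "-")) -1 else 1
      loadings[members, cc$from] <- loadings[members, cc$from] + sgn * cc$strength
    }
    resid[members] <- sqrt(1 - b$within_r)
  }
  list(loadings = loadings, resid = resid)
}

# Latent Gaussian copula scores for the sites of one group: taxa x sites
# matrix of N(0,1) marginals with the block_loadings() correlation structure.
latent_scores <- function(scenario, taxonomy, group, n_sites) {
  ld <- block_loadings(scenario, taxonomy, group)
  n_taxa <- nrow(ld$loadings)
  eps <- matrix(rnorm(n_taxa * n_sites), n_taxa, n_sites,
                dimnames = list(rownames(ld$loadings), NULL))
  f <- matrix(rnorm(ncol(ld$loadings) * n_sites), ncol(ld$loadings), n_sites)
  ld$loadings %*% f + ld$resid * eps
}

# Enumerate every pair carrying planted (direct or implied) latent
# correlation, per group, from the factor loadings.
planted_edges <- function(scenario, taxonomy) {
  groups <- names(scenario$n_sites_per_group)
  purrr::map_dfr(groups, function(g) {
    ld <- block_loadings(scenario, taxonomy, g)
    sigma <- tcrossprod(ld$loadings)
    idx <- which(upper.tri(sigma) & abs(sigma) > 1e-9, arr.ind = TRUE)
    if (!nrow(idx)) {
      return(tibble::tibble(group = character(), taxon_i = character(),
                            taxon_j = character(), latent_r = numeric(), sign = character()))
    }
    r <- sigma[idx]
    tibble::tibble(group = g, taxon_i = rownames(sigma)[idx[, 1]],
                   taxon_j = rownames(sigma)[idx[, 2]],
                   latent_r = r, sign = ifelse(r >= 0, "+", "-"))
  })
}

#' Generate synthetic phytoplankton and bacterial communities
#'
#' Draws taxa-by-site count tables whose composition tracks each site's true
#' TSI: a logistic diatom-to-cyanobacteria turnover for phytoplankton,
#' Proteobacteria-dominated bacterial profiles whose within-phylum evenness
#' (hence Shannon diversity) declines with TSI, and a Gaussian copula with
#' planted signed block correlations driving negative-binomial count
#' marginals. Bacterial columns are scaled to the scenario's library size in
#' expectation; phytoplankton counts emulate microscopy counting units.
#'
#' @param scenario A [gradient_scenario()].
#' @param truth The `truth` tibble from [generate_chemistry()] (site, group
#'   and target TSI).
#' @param seed Integer seed.
#' @return A list: `phyto` and `bacteria` count tibbles (first column
#'   `taxon_id`, one column per site), `taxonomy`, and `truth` (list with
#'   `blocks`, `planted_edges`, `dominance`).
#' @export
generate_communities <- function(scenario, truth, seed = 1) {
  stopifnot(inherits(scenario, "gradient_scenario"),
            all(c("site_id", "group", "target_tsi") %in% names(truth)))
  taxonomy <- build_taxonomy(scenario)
  profiles <- expected_profiles(scenario, taxonomy, truth$group)
  with_stage_seed(seed, "communities", {
    z <- matrix(NA_real_, nrow(taxonomy), nrow(truth),
                dimnames = list(taxonomy$taxon_id, truth$site_id))
    for (g in unique(truth$group)) {
      idx <- which(truth$group == g)
      z[, idx] <- latent_scores(scenario, taxonomy, g, length(idx))
    }
    u <- pnorm(z)
    phy_ids <- taxonomy$taxon_id[taxonomy$kingdom == "phytoplankton"]
    bac_ids <- taxonomy$taxon_id[taxonomy$kingdom == "bacteria"]
    mu_phy <- profiles$phyto * scenario$phyto_total
    mu_bac <- profiles$bact * scenario$library_size
    counts_phy <- matrix(
      qnbinom(u[phy_ids, ], size = scenario$phyto_dispersion, mu = mu_phy),
      nrow(mu_phy), dimnames = list(phy_ids, truth$site_id)
    )
    counts_bac <- matrix(
      qnbinom(u[bac_ids, ], size = scenario$nb_dispersion, mu = mu_bac),
      nrow(mu_bac), dimnames = list(bac_ids, truth$site_id)
    )
    list(
      phyto = counts_tibble(counts_phy),
      bacteria = counts_tibble(counts_bac),
      taxonomy = taxonomy[, c("taxon_id", "kingdom", "phylum", "genus")],
      truth = list(
        blocks = taxonomy[, c("taxon_id", "block")],
        planted_edges = planted_edges(scenario, taxonomy),
        dominance = dplyr::bind_cols(truth[, c("site_id", "group", "target_tsi")],
                                     profiles$dominance)
      )
    )
  })
}

#' Simulate a complete gradient survey dataset
#'
#' Chains [generate_chemistry()] and [generate_communities()] into one
#' deterministic dataset: chemistry, both count tables, taxonomy, per-sample
#' group labels and the truth sidecar sufficient to score recovery exactly.
#'
#' @param scenario A [gradient_scenario()].
#' @param seed Integer seed; identical `(scenario, seed)` yields an identical
#'   dataset.
#' @return A `gradient_dataset` list: `chemistry`, `phyto`, `bacteria`,
#'   `taxonomy`, `groups` (tibble `sample_id`, `group`), `truth` (list with
#'   `sites`, `blocks`, `planted_edges`, `dominance`), `scenario`, `seed`.
#' @export
simulate_dataset <- function(scenario = gradient_scenario(), seed = 1) {
  chem <- generate_chemistry(scenario, seed)
  comm <- generate_communities(scenario, chem$truth, seed)
  structure(
    list(
      chemistry = chem$chemistry,
      phyto = comm$phyto,
      bacteria = comm$bacteria,
      taxonomy = comm$taxonomy,
      groups = tibble::tibble(sample_id = chem$truth$site_id, group = chem$truth$group),
      truth = c(list(sites = chem$truth), comm$truth),
      scenario = scenario,
      seed = seed
    ),
    class = "gradient_dataset"
  )
}

#' Run the full analysis pipeline on an in-memory dataset
#'
#' Convenience wrapper chaining the analysis stages on a dataset (simulated or
#' loaded): trophic assessment, bacterial rarefaction, alpha diversity,
#' pooled abundance filtering, per-group signed networks, topology metrics and
#' the cross-group trend comparison.
#'
#' @param dataset A `gradient_dataset` (or a list with the same elements).
#' @param rarefaction_depth Reads per sample for bacterial rarefaction
#'   (default 27000).
#' @param min_rel Abundance filter threshold (default 1e-4).
#' @param threshold_r,alpha Network edge gates (defaults 0.6, 0.05).
#' @param restarts Louvain restarts (default 10).
#' @param seed Seed for the stochastic stages (rarefaction, Louvain).
#' @return A list: `assessment`, `summary`, `diversity_phyto`,
#'   `diversity_bact`, `networks` (per group), `topologies` (tibble),
#'   `cross_kingdom` (per group), `comparison`.
#' @export
analyze_dataset <- function(dataset, rarefaction_depth = 27000, min_rel = 1e-4,
                            threshold_r = 0.6, alpha = 0.05, restarts = 10, seed = 1) {
  assessment <- assess_sites(dataset$chemistry)
  bact_rare <- rarefy(dataset$bacteria, depth = rarefaction_depth, seed = seed)
  combined <- dplyr::bind_rows(dataset$phyto, dataset$bacteria)
  filtered <- filter_low_abundance(combined, dataset$taxonomy, min_rel = min_rel)
  groups <- unique(dataset$groups$group)
  networks <- lapply(setNames(groups, groups), function(g) {
    samp <- dataset$groups$sample_id[dataset$groups$group == g]
    build_network(filtered[, c(names(filtered)[1], samp)], dataset$taxonomy,
                  group = g, threshold_r = threshold_r, alpha = alpha)
  })
  topologies <- dplyr::bind_rows(lapply(networks, topology, restarts = restarts, seed = seed))
  list(
    assessment = assessment,
    summary = trophic_summary(assessment),
    diversity_phyto = diversity_table(dataset$phyto),
    diversity_bact = diversity_table(bact_rare),
    networks = networks,
    topologies = topologies,
    cross_kingdom = lapply(networks, cross_kingdom_composition),
    comparison = if (length(networks) >= 2) compare_topologies(topologies) else NULL
  )
}

#' Score recovery of planted truth
#'
#' Compares pipeline outputs against the truth sidecar of the dataset they
#' were computed from: trophic class accuracy; per-group planted-edge recall,
#' precision, sign accuracy and spurious-edge rate (detected edges among
#' never-correlated pairs); and the direction of the bacterial Shannon,
#' modularity and negative-edge-percentage trends across groups in
#' low-to-high order.
#'
#' @param analysis Output of [analyze_dataset()].
#' @param dataset The `gradient_dataset` the analysis was run on.
#' @return A `recovery_report` list with elements `class_accuracy`, `edges`
#'   (per-group tibble), `trends` (named logical vector) and `group_order`.
#' @export
score_recovery <- function(analysis, dataset) {
  truth <- dataset$truth
  assessment <- analysis$assessment
  if (!setequal(assessment$site_id, truth$sites$site_id)) {
    abort("assessment and truth refer to different site sets")
  }
  lab <- setNames(as.character(assessment$label), assessment$site_id)
  class_accuracy <- mean(lab[truth$sites$site_id] == truth$sites$true_label)

  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")
  edges <- purrr::map_dfr(names(analysis$networks), function(g) {
    net <- analysis$networks[[g]]
    truth_g <- truth$planted_edges[truth$planted_edges$group == g, ]
    node_ids <- net$nodes$taxon_id
    truth_g <- truth_g[truth_g$taxon_i %in% node_ids & truth_g$taxon_j %in% node_ids, ]
    tk <- pair_key(truth_g$taxon_i, truth_g$taxon_j)
    dk <- pair_key(net$edges$taxon_i, net$edges$taxon_j)
    n_pairs <- length(node_ids) * (length(node_ids) - 1) / 2
    hit <- dk %in% tk
    truth_sign <- setNames(truth_g$sign, tk)
    tibble::tibble(
      group = g,
      n_planted = length(tk),
      n_detected = length(dk),
      recall = if (length(tk)) mean(tk %in% dk) else NA_real_,
      precision = if (length(dk)) mean(hit) else NA_real_,
      sign_accuracy = if (any(hit)) mean(net$edges$sign[hit] == truth_sign[dk[hit]]) else NA_real_,
      spurious_rate = sum(!hit) / (n_pairs - length(tk))
    )
  })

  ord <- intersect(c("L", "M", "H"), unique(dataset$groups$group))
  shannon_by_group <- vapply(ord, function(g) {
    samp <- dataset$groups$sample_id[dataset$groups$group == g]
    mean(analysis$diversity_bact$shannon[analysis$diversity_bact$sample_id %in% samp])
  }, 1)
  topo <- analysis$topologies[match(ord, analysis$topologies$group), ]
  trends <- c(
    shannon_decreasing = trend_flag(shannon_by_group) == "decreasing",
    modularity_decreasing = trend_flag(topo$modularity) == "decreasing",
    pct_negative_increasing = trend_flag(topo$pct_negative_edges) == "increasing"
  )
  structure(
    list(class_accuracy = class_accuracy, edges = edges, trends = trends, group_order = ord),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery report: class accuracy %.3f\n", x$class_accuracy))
  print(x$edges)
  cat("Trends (", paste(x$group_order, collapse = " -> "), "): ",
      paste(names(x$trends)[x$trends], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.recovery_report <- function(x, ...) {
  dplyr::mutate(x$edges, class_accuracy = x$class_accuracy)
}
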