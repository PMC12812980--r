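#' Assemble a pipeline configuration
#'
#' Either `scenario` (synthetic run) or the five input paths (chemistry,
#' phytoplankton counts, bacterial counts, taxonomy, groups) must be given.
#' All analysis defaults mirror the survey protocol: rarefaction to 27000
#' reads, 0.01% abundance filter, Spearman `|rho| >= 0.6` with FDR-adjusted
#' `p < 0.05`, 999 permutations, 10 Louvain restarts.
#'
#' @param chemistry,phyto,bacteria,taxonomy,groups Input file paths.
#' @param scenario A [gradient_scenario()] (or a YAML/JSON path of scenario
#'   fields) for a synthetic run.
#' @param rarefaction_depth,filter_min_rel,edge_threshold,alpha,n_perm,louvain_restarts
#'   Analysis parameters.
#' @param seed Run seed; every stochastic stage derives its substream from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(chemistry = NULL, phyto = NULL, bacteria = NULL,
                            taxonomy = NULL, groups = NULL, scenario = NULL,
                            rarefaction_depth = 27000, filter_min_rel = 1e-4,
                            edge_threshold = 0.6, alpha = 0.05, n_perm = 999,
                            louvain_restarts = 10, seed = 1, out_dir = "trophicnet_out") {
  stopifnot(rarefaction_depth >= 1, filter_min_rel >= 0, filter_min_rel < 1,
            edge_threshold > 0, edge_threshold <= 1, alpha > 0, alpha < 1, n_perm >= 1)
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  cfg <- list(
    chemistry = chemistry, phyto = phyto, bacteria = bacteria,
    taxonomy = taxonomy, groups = groups, scenario = scenario,
    rarefaction_depth = rarefaction_depth, filter_min_rel = filter_min_rel,
    edge_threshold = edge_threshold, alpha = alpha, n_perm = n_perm,
    louvain_restarts = louvain_restarts, seed = as.integer(seed), out_dir = out_dir
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a scenario configuration file
#'
#' YAML or JSON file whose fields mirror the [gradient_scenario()] arguments;
#' absent fields keep their defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `gradient_scenario`.
#' @export
read_scenario <- function(path) {
  fields <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(fields$n_sites_per_group)) {
    fields$n_sites_per_group <- unlist(fields$n_sites_per_group)
  }
  if (!is.null(fields$target_tsi_ranges)) {
    fields$target_tsi_ranges <- lapply(fields$target_tsi_ranges, as.numeric)
  }
  do.call(gradient_scenario, fields)
}

#' Run the full assessment and network pipeline
#'
#' Executes the stages end to end — trophic assessment, bacterial
#' rarefaction, alpha diversity, Bray-Curtis matrices, pooled abundance
#' filtering, per-group signed networks, topology, cross-kingdom composition,
#' trend comparison and environment-community permutation tests — and writes
#' every result plus a run manifest (package version, seed, config hash) to
#' the output directory. The same config and seed always reproduce identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the in-memory result bundle of [analyze_dataset()] plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  result <- tryCatch({
    dataset <- if (!is.null(config$scenario)) {
      simulate_dataset(config$scenario, seed = config$seed)
    } else {
      for (f in c("chemistry", "phyto", "bacteria", "taxonomy", "groups")) {
        if (is.null(config[[f]])) abort(paste0("config lacks input path: ", f))
      }
      structure(list(
        chemistry = read_chemistry(config$chemistry),
        phyto = read_counts(config$phyto),
        bacteria = read_counts(config$bacteria),
        taxonomy = read_taxonomy(config$taxonomy),
        groups = read_groups(config$groups)
      ), class = "gradient_dataset")
    }
    if (!is.null(config$scenario)) write_dataset(dataset, file.path(config$out_dir, "dataset"))

    stage <- "analyze"
    analysis <- analyze_dataset(
      dataset,
      rarefaction_depth = config$rarefaction_depth,
      min_rel = config$filter_min_rel,
      threshold_r = config$edge_threshold,
      alpha = config$alpha,
      restarts = config$louvain_restarts,
      seed = config$seed
    )

    stage <- "distances"
    bact_rare <- rarefy(dataset$bacteria, depth = config$rarefaction_depth, seed = config$seed)
    d_bact <- bray_curtis(bact_rare)
    d_phyto <- bray_curtis(dataset$phyto, transform = "relative")

    stage <- "env_tests"
    shared <- colnames(d_bact)
    env_cols <- setdiff(names(dataset$chemistry), "site_id")
    env_tests <- purrr::map_dfr(env_cols, function(v) {
      env <- dataset$chemistry[[v]][match(shared, dataset$chemistry$site_id)]
      res <- env_community_correlation(env, d_bact, n_perm = config$n_perm,
                                       seed = derive_seed(config$seed, paste0("env_", v)))
      dplyr::mutate(tidy(res), variable = v, community = "bacteria", .before = 1)
    })

    stage <- "write"
    out <- config$out_dir
    readr::write_csv(tidy(analysis$assessment), file.path(out, "assessment.csv"))
    readr::write_csv(analysis$diversity_phyto, file.path(out, "diversity_phyto.csv"))
    readr::write_csv(analysis$diversity_bact, file.path(out, "diversity_bacteria.csv"))
    write_distance_matrix(d_bact, file.path(out, "bray_curtis_bacteria.tsv"))
    write_distance_matrix(d_phyto, file.path(out, "bray_curtis_phyto.tsv"))
    readr::write_csv(env_tests, file.path(out, "env_community_tests.csv"))
    for (g in names(analysis$networks)) {
      net <- analysis$networks[[g]]
      readr::write_csv(net$edges, file.path(out, paste0("edges_", g, ".csv")))
      write_network_graphml(net, file.path(out, paste0("network_", g, ".graphml")))
      write_network_gexf(net, file.path(out, paste0("network_", g, ".gexf")))
    }
    jsonlite::write_json(analysis$topologies, file.path(out, "topology.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    if (!is.null(analysis$comparison)) {
      readr::write_csv(analysis$comparison, file.path(out, "topology_trends.csv"))
    }
    jsonlite::write_json(trophic_summary(analysis$assessment), file.path(out, "trophic_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)

    manifest <- list(
      package = "trophicnet",
      version = as.character(utils::packageVersion("trophicnet")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      config = config_for_manifest(config),
      created = "run manifest; re-running with this config and seed reproduces all outputs"
    )
    writeLines(yaml::as.yaml(manifest), file.path(out, "manifest.yml"))
    c(analysis, list(env_tests = env_tests, manifest = manifest))
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ", conditionMessage(e)))
  })
  invisible(result)
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$scenario)) cfg$scenario <- unclass(cfg$scenario)
  cfg
}

#' Command-line entry point
#'
#' Thin argv-based dispatcher over the package's module entry points, used by
#' the `inst/scripts/trophicnet` Rscript wrapper. Subcommands:
#'
#' * `tsi --in chem.csv --out report.json` — per-site assessment + summary
#' * `diversity --in counts.csv --out div.csv` — richness and Shannon
#' * `network --counts counts.csv --taxonomy tax.csv --out edges.csv`
#' * `mantel --d1 a.tsv --d2 b.tsv [--control c.tsv] --out res.json`
#' * `simulate --scenario s.yml --seed 7 --out dir` — dataset + truth sidecar
#' * `run --config cfg.yml` or `run --scenario s.yml --out dir` — full pipeline
#'
#' Messages go to stderr; the function never calls `quit()` and instead
#' returns the exit code (0 success, 1 runtime error, 2 usage error).
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: trophicnet <subcommand> [flags]",
    "subcommands: tsi, diversity, network, mantel, simulate, run",
    "common flags: --seed <int> --out <path> --config <path>", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  sub <- args[1]
  if (!sub %in% c("tsi", "diversity", "network", "mantel", "simulate", "run")) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  flags <- tryCatch(parse_flags(args[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n", usage)
    return(invisible(2L))
  }
  required <- switch(sub,
    tsi = c("in", "out"), diversity = c("in", "out"),
    network = c("counts", "taxonomy", "out"), mantel = c("d1", "d2", "out"),
    simulate = "out",
    run = if (is.null(flags$config)) c("scenario", "out") else character()
  )
  missing_keys <- setdiff(required, names(flags))
  if (length(missing_keys)) {
    message("missing required flag(s): ", paste0("--", missing_keys, collapse = ", "), "\n", usage)
    return(invisible(2L))
  }
  seed <- as.integer(flags$seed %||% 1L)
  code <- tryCatch({
    switch(sub,
      tsi = {
        assessment <- assess_sites(read_chemistry(flags[["in"]]))
        jsonlite::write_json(
          list(sites = tidy(assessment), summary = trophic_summary(assessment)),
          flags$out, dataframe = "rows", auto_unbox = TRUE, digits = NA)
        0L
      },
      diversity = {
        readr::write_csv(diversity_table(read_counts(flags[["in"]])), flags$out)
        0L
      },
      network = {
        net <- build_network(
          filter_low_abundance(read_counts(flags$counts), read_taxonomy(flags$taxonomy),
                               min_rel = as.numeric(flags$min_rel %||% 1e-4)),
          read_taxonomy(flags$taxonomy),
          threshold_r = as.numeric(flags$threshold %||% 0.6),
          alpha = as.numeric(flags$alpha %||% 0.05))
        readr::write_csv(net$edges, flags$out)
        0L
      },
      mantel = {
        d1 <- read_distance_matrix(flags$d1)
        d2 <- read_distance_matrix(flags$d2)
        n_perm <- as.integer(flags$n_perm %||% 999L)
        res <- if (!is.null(flags$control)) {
          partial_mantel(d1, d2, read_distance_matrix(flags$control), n_perm = n_perm, seed = seed)
        } else {
          mantel_test(d1, d2, n_perm = n_perm, seed = seed)
        }
        jsonlite::write_json(tidy(res), flags$out, dataframe = "rows", auto_unbox = TRUE, digits = NA)
        0L
      },
      simulate = {
        scenario <- if (!is.null(flags$scenario)) read_scenario(flags$scenario) else gradient_scenario()
        write_dataset(simulate_dataset(scenario, seed = seed), flags$out)
        0L
      },
      run = {
        cfg <- if (!is.null(flags$config)) {
          fields <- yaml::read_yaml(flags$config)
          do.call(pipeline_config, fields)
        } else {
          pipeline_config(scenario = flags$scenario, seed = seed, out_dir = flags$out)
        }
        run_pipeline(cfg)
        0L
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i + 1 > length(args) || startsWith(args[i + 1], "--")) {
      stop("flag --", key, " needs a value", call. = FALSE)
    }
    flags[[key]] <- args[i + 1]
    i <- i + 2
  }
  flags
}
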