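# Delimited-text readers with load-time validation.  Comma or tab is
# auto-detected from the header line; UTF-8; header row required.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1, encoding = "UTF-8")
  if (!length(first)) abort(paste0(path, ": empty file"))
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

read_delim_checked <- function(path, required, label) {
  if (!file.exists(path)) abort(paste0(label, " file not found: ", path))
  df <- readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE,
                          progress = FALSE, locale = readr::locale(encoding = "UTF-8"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("%s (%s): missing column(s) %s", label, path,
                  paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Read a water-chemistry table
#'
#' Delimited text with a header row and columns `site_id`, `tn`, `tp`,
#' `chl_a`, `secchi` (any further covariate columns are kept). An optional
#' second header row of unit strings (`mg/L`, `ug/L`, `m`) is validated and
#' removed. Positivity of the four TSI fields and uniqueness of `site_id` are
#' enforced at load with the offending site named.
#'
#' @param path File path (comma- or tab-separated, auto-detected).
#' @return A chemistry tibble ready for [assess_sites()].
#' @export
read_chemistry <- function(path) {
  df <- read_delim_checked(path, c("site_id", "tn", "tp", "chl_a", "secchi"), "chemistry")
  # optional units row directly under the header
  if (nrow(df) && is_units_row(df[1, ])) {
    validate_units_row(df[1, ], path)
    df <- df[-1, , drop = FALSE]
    df <- dplyr::mutate(df, dplyr::across(-"site_id", as.numeric))
  }
  if (!nrow(df)) abort(paste0("chemistry (", path, "): no data rows"))
  ids <- as.character(df$site_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) abort(paste0("chemistry (", path, "): duplicate site_id ", paste(dup, collapse = ", ")))
  for (col in c("tn", "tp", "chl_a", "secchi")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      abort(sprintf("chemistry (%s) line %d: invalid %s for site %s",
                    path, bad[1] + 1L, col, ids[bad[1]]))
    }
    df[[col]] <- v
  }
  tibble::as_tibble(df)
}

is_units_row <- function(row) {
  vals <- suppressWarnings(as.numeric(unlist(row[-1])))
  all(is.na(vals))
}

validate_units_row <- function(row, path) {
  expected <- c(tn = "mg/L", tp = "mg/L", chl_a = "ug/L", secchi = "m")
  canon <- function(x) gsub("μ", "u", tolower(trimws(x)))
  for (col in names(expected)) {
    got <- canon(row[[col]])
    if (!is.na(got) && nzchar(got) && got != tolower(expected[[col]])) {
      abort(sprintf("chemistry (%s): column %s declares unit '%s', expected %s",
                    path, col, row[[col]], expected[[col]]))
    }
  }
}

#' Read a taxa-by-sample count table
#'
#' Delimited text, taxa as rows, samples as columns, first column `taxon_id`.
#' Duplicate taxon ids, missing values and negative counts are rejected with
#' the offending line identified.
#'
#' @param path File path.
#' @return A count tibble.
#' @export
read_counts <- function(path) {
  df <- read_delim_checked(path, "taxon_id", "counts")
  if (ncol(df) < 2) abort(paste0("counts (", path, "): no sample columns"))
  ids <- as.character(df$taxon_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) abort(paste0("counts (", path, "): duplicate taxon_id ", paste(dup, collapse = ", ")))
  for (col in setdiff(names(df), "taxon_id")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort(sprintf("counts (%s) line %d: negative or missing count in sample %s",
                    path, bad[1] + 1L, col))
    }
  }
  tibble::as_tibble(df)
}

#' Read a taxonomy map
#'
#' Columns `taxon_id`, `kingdom` (`phytoplankton` / `bacteria`), `phylum` and
#' optionally `genus`.
#'
#' @param path File path.
#' @return A taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  df <- read_delim_checked(path, c("taxon_id", "kingdom", "phylum"), "taxonomy")
  ids <- as.character(df$taxon_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) abort(paste0("taxonomy (", path, "): duplicate taxon_id ", paste(dup, collapse = ", ")))
  bad <- !df$kingdom %in% c("phytoplankton", "bacteria")
  if (any(bad)) {
    abort(paste0("taxonomy (", path, "): unknown kingdom for ", paste(ids[bad], collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Read per-sample trophic group labels
#'
#' Columns `sample_id` and `group` with values `L`, `M` or `H`.
#'
#' @param path File path.
#' @return A groups tibble.
#' @export
read_groups <- function(path) {
  df <- read_delim_checked(path, c("sample_id", "group"), "groups")
  bad <- !df$group %in% c("L", "M", "H")
  if (any(bad)) {
    abort(paste0("groups (", path, "): group labels must be L/M/H; offending sample(s): ",
                 paste(df$sample_id[bad], collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Write a labelled square distance matrix as delimited text
#'
#' @param d Square matrix with dimnames.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- tibble::as_tibble(as.data.frame(d), rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a labelled square distance matrix
#'
#' @param path File written by [write_distance_matrix()] (first column the
#'   row labels).
#' @return A square numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- read_delim_checked(path, character(), "distance matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  check_distance_matrix(m, path)
}

#' Export a co-occurrence network as GraphML
#'
#' Nodes carry `kingdom` and `phylum` attributes; edges carry `rho`, `q` and
#' `sign` — the attribute set Gephi-style tools expect.
#'
#' @param network A `cooccurrence_network`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export a co-occurrence network as GEXF
#'
#' Minimal GEXF 1.3 with the same node (`kingdom`, `phylum`) and edge
#' (`rho`, `q`, `sign`) attributes as the GraphML export.
#'
#' @inheritParams write_network_graphml
#' @param path Output `.gexf` path.
#' @return `path`, invisibly.
#' @export
write_network_gexf <- function(network, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://gexf.net/1.3", version = "1.3")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs_n <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs_n, "attribute", id = "kingdom", title = "kingdom", type = "string")
  xml2::xml_add_child(attrs_n, "attribute", id = "phylum", title = "phylum", type = "string")
  attrs_e <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(attrs_e, "attribute", id = "rho", title = "rho", type = "double")
  xml2::xml_add_child(attrs_e, "attribute", id = "q", title = "q", type = "double")
  xml2::xml_add_child(attrs_e, "attribute", id = "sign", title = "sign", type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(network$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = network$nodes$taxon_id[i],
                              label = network$nodes$taxon_id[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "kingdom", value = network$nodes$kingdom[i])
    xml2::xml_add_child(av, "attvalue", `for` = "phylum", value = network$nodes$phylum[i] %||% "")
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(network$edges))) {
    ed <- xml2::xml_add_child(edges, "edge",
                              id = as.character(i - 1L),
                              source = network$edges$taxon_i[i],
                              target = network$edges$taxon_j[i])
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "rho", value = format(network$edges$rho[i], digits = 10))
    xml2::xml_add_child(av, "attvalue", `for` = "q", value = format(network$edges$q[i], digits = 10))
    xml2::xml_add_child(av, "attvalue", `for` = "sign", value = network$edges$sign[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a gradient dataset to a directory
#'
#' Writes the chemistry, count, taxonomy and group tables of a simulated
#' dataset as delimited text plus the truth sidecar as JSON, the on-disk
#' counterpart of [simulate_dataset()].
#'
#' @param dataset A `gradient_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$chemistry, file.path(dir, "chemistry.csv"))
  readr::write_csv(dataset$phyto, file.path(dir, "phyto_counts.csv"))
  readr::write_csv(dataset$bacteria, file.path(dir, "bacteria_counts.csv"))
  readr::write_csv(dataset$taxonomy, file.path(dir, "taxonomy.csv"))
  readr::write_csv(dataset$groups, file.path(dir, "groups.csv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a gradient dataset from a directory
#'
#' @param dir Directory written by [write_dataset()] (truth sidecar optional).
#' @return A `gradient_dataset`-shaped list (without `scenario`).
#' @export
read_dataset <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  structure(
    list(
      chemistry = read_chemistry(file.path(dir, "chemistry.csv")),
      phyto = read_counts(file.path(dir, "phyto_counts.csv")),
      bacteria = read_counts(file.path(dir, "bacteria_counts.csv")),
      taxonomy = read_taxonomy(file.path(dir, "taxonomy.csv")),
      groups = read_groups(file.path(dir, "groups.csv")),
      truth = if (file.exists(truth_path)) {
        tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
        tr[c("sites", "blocks", "planted_edges", "dominance")] <-
          lapply(tr[c("sites", "blocks", "planted_edges", "dominance")], tibble::as_tibble)
        tr
      }
    ),
    class = "gradient_dataset"
  )
}
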