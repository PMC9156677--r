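#' Read a cohort study from delimited text files
#'
#' Tables are TSV or CSV (chosen from the file extension, `.csv` means
#' comma), first row a header, first column the sample identifier. The
#' metadata file must contain columns `sample_id` and `cohort`. Samples
#' present in one file but not another raise an alignment error naming the
#' offending sample; they are never silently dropped.
#'
#' @param abundance_path path to the species abundance table.
#' @param metadata_path path to the sample metadata table.
#' @param metabolite_path optional path to the metabolite table.
#' @return a [cohort_study()].
#' @export
read_cohort_study <- function(abundance_path, metadata_path,
                              metabolite_path = NULL) {
  meta <- read_delim_auto(metadata_path)
  if (!"sample_id" %in% names(meta)) names(meta)[1] <- "sample_id"
  abund <- read_delim_auto(abundance_path)
  metab <- if (!is.null(metabolite_path)) read_delim_auto(metabolite_path)
  cohort_study(abund, meta, metab)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Write a samples-by-features table to delimited text
#'
#' @param tbl data frame with a `sample_id` column.
#' @param path output path; `.csv` selects comma, anything else tab.
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(tibble::as_tibble(tbl), path, progress = FALSE)
  } else {
    readr::write_tsv(tibble::as_tibble(tbl), path, progress = FALSE)
  }
  invisible(path)
}

#' Run configuration for the pipeline
#'
#' Collects every tunable the pipeline stages consume, so one object can be
#' threaded through an analysis and echoed into reports. The defaults are
#' the study conditions: 999 permutations, two-stage FDR at 10%, node
#' prevalence at 5%, 100 Louvain iterations at resolution 1, 5x5 double
#' cross-validation with 50 repeats.
#'
#' @param seed integer seed used by every randomized stage.
#' @param n_permutations permutations for PERMANOVA/ANOSIM.
#' @param fdr_level two-stage Benjamini-Hochberg level for edge pruning.
#' @param prevalence_min minimum fraction of samples a species must be
#'   detected in to become a network node.
#' @param louvain_iterations number of Louvain runs entering the consensus.
#' @param louvain_resolution Louvain resolution parameter.
#' @param cv_outer,cv_inner fold counts of the double cross-validation.
#' @param cv_repeats repeats of the double cross-validation.
#' @param max_components largest PLS component count the inner loop may pick.
#' @param out_dir optional output directory recorded in reports.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_permutations = 999L, fdr_level = 0.10,
                       prevalence_min = 0.05, louvain_iterations = 100L,
                       louvain_resolution = 1.0, cv_outer = 5L, cv_inner = 5L,
                       cv_repeats = 50L, max_components = 5L, out_dir = NULL) {
  stopifnot(n_permutations >= 1, fdr_level > 0, fdr_level < 1,
            prevalence_min >= 0, prevalence_min <= 1,
            louvain_iterations >= 1, louvain_resolution > 0,
            cv_outer >= 2, cv_inner >= 2, cv_repeats >= 1,
            max_components >= 1)
  structure(list(seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 fdr_level = fdr_level, prevalence_min = prevalence_min,
                 louvain_iterations = as.integer(louvain_iterations),
                 louvain_resolution = louvain_resolution,
                 cv_outer = as.integer(cv_outer),
                 cv_inner = as.integer(cv_inner),
                 cv_repeats = as.integer(cv_repeats),
                 max_components = as.integer(max_components),
                 out_dir = out_dir),
            class = "run_config")
}

#' Write an analysis report as JSON
#'
#' Serializes a named collection of results (test results, PLS-DA
#' summaries, network summaries, plain values) together with an echo of the
#' run configuration, so every statistic is stored next to the seed and
#' thresholds that produced it.
#'
#' @param results named list; `sig_test`, `sig_plsda` and `sig_network`
#'   objects are summarized via their [tidy()]/[glance()] methods, other
#'   entries are written as is.
#' @param path output path for the JSON file.
#' @param config a [run_config()] echoed under `$config`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = run_config()) {
  ser <- lapply(results, function(r) {
    if (inherits(r, "sig_test")) {
      as.list(tidy(r))
    } else if (inherits(r, "sig_plsda")) {
      as.list(glance(r))
    } else if (inherits(r, "sig_network")) {
      summary_network(r)
    } else if (inherits(r, "sig_double_cv")) {
      as.list(tidy(r))
    } else if (is.data.frame(r)) {
      r
    } else {
      r
    }
  })
  payload <- c(list(config = unclass(config)[!vapply(config, is.null, TRUE)]),
               ser)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

summary_network <- function(net) {
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       n_sigs = if (!is.null(net$partition)) {
         length(unique(net$partition$membership$sig))
       } else NA)
}

#' Export a species network to GEXF or GraphML
#'
#' Node attributes carried: cohort affinity, prevalence, degree,
#' betweenness, keystonness and SIG id; edge attributes: Pearson r,
#' leave-one-out averaged p, FDR q, sign and the 1-8 thickness category.
#' GraphML goes through \pkg{igraph}; GEXF (the Gephi-native dialect) is
#' written directly.
#'
#' @param net a `sig_network` (see [build_network()]).
#' @param path output file path.
#' @param format `"gexf"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("gexf", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "sig_network"))
  if (nrow(net$nodes) < 1) abort("Network has no nodes.")
  g <- network_igraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(net, path)
  }
  invisible(path)
}

# igraph view of a sig_network, with all node/edge attributes attached.
network_igraph <- function(net) {
  nodes <- as.data.frame(net$nodes)
  edges <- as.data.frame(net$edges)
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges) > 0) edges else
      data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = nodes
  )
  g
}

write_gexf <- function(net, path) {
  doc <- xml2::xml_new_root(
    "gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2"
  )
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                               mode = "static")
  node_attrs <- setdiff(names(net$nodes), "species")
  edge_attrs <- setdiff(names(net$edges), c("from", "to"))

  natt <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (i in seq_along(node_attrs)) {
    xml2::xml_add_child(natt, "attribute", id = as.character(i - 1L),
                        title = node_attrs[i],
                        type = gexf_type(net$nodes[[node_attrs[i]]]))
  }
  eatt <- xml2::xml_add_child(graph, "attributes", class = "edge")
  for (i in seq_along(edge_attrs)) {
    xml2::xml_add_child(eatt, "attribute", id = as.character(i - 1L),
                        title = edge_attrs[i],
                        type = gexf_type(net$edges[[edge_attrs[i]]]))
  }

  nodes <- xml2::xml_add_child(graph, "nodes")
  for (k in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = net$nodes$species[k],
                              label = net$nodes$species[k])
    av <- xml2::xml_add_child(nd, "attvalues")
    for (i in seq_along(node_attrs)) {
      xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                          value = gexf_value(net$nodes[[node_attrs[i]]][k]))
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (k in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(edges, "edge", id = as.character(k - 1L),
                              source = net$edges$from[k],
                              target = net$edges$to[k])
    av <- xml2::xml_add_child(ed, "attvalues")
    for (i in seq_along(edge_attrs)) {
      xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                          value = gexf_value(net$edges[[edge_attrs[i]]][k]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

gexf_type <- function(x) {
  if (is.numeric(x)) "double" else "string"
}

gexf_value <- function(x) {
  if (is.numeric(x)) format(x, digits = 17) else as.character(x)
}

#' Read a GEXF network written by [write_network()]
#'
#' Round-trip companion of the GEXF writer; mostly useful for checking that
#' exports preserve the node and edge attribute values.
#'
#' @param path GEXF file path.
#' @return list with tibbles `nodes` and `edges`.
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  attr_titles <- function(cls) {
    nodeset <- xml2::xml_find_all(
      doc, sprintf(".//attributes[@class='%s']/attribute", cls))
    setNames(xml2::xml_attr(nodeset, "title"), xml2::xml_attr(nodeset, "id"))
  }
  ntitles <- attr_titles("node")
  etitles <- attr_titles("edge")
  parse_elems <- function(xpath, id_fields, titles) {
    elems <- xml2::xml_find_all(doc, xpath)
    rows <- lapply(elems, function(e) {
      base <- lapply(id_fields, function(f) xml2::xml_attr(e, f))
      names(base) <- names(id_fields)
      avs <- xml2::xml_find_all(e, "./attvalues/attvalue")
      vals <- setNames(xml2::xml_attr(avs, "value"),
                       titles[xml2::xml_attr(avs, "for")])
      c(base, as.list(vals))
    })
    out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    for (nm in names(out)) {
      num <- suppressWarnings(as.numeric(out[[nm]]))
      if (!anyNA(num) && nm != names(id_fields)[1]) out[[nm]] <- num
    }
    out
  }
  nodes <- parse_elems(".//nodes/node", c(species = "id"), ntitles)
  edges <- parse_elems(".//edges/edge", c(from = "source", to = "target"),
                       etitles)
  list(nodes = nodes, edges = edges)
}

#' Read a run configuration from a YAML file
#'
#' The file holds any subset of the [run_config()] fields; missing fields
#' take their defaults, unknown fields raise an error.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration field(s): ", toString(unknown)))
  }
  do.call(run_config, vals)
}
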