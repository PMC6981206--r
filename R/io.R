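#' Write a pipeline table as TSV with a provenance header
#'
#' All tabular outputs share one dialect: tab-separated values preceded by
#' `#`-prefixed metadata lines recording the producing stage and a hash of
#' the configuration, so every file declares where it came from.
#'
#' @param x A tibble.
#' @param path Output path.
#' @param stage Name of the producing stage.
#' @param config Object whose hash is recorded (may be NULL).
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(x, path, stage = "ppirewire", config = NULL) {
  header <- c(
    sprintf("# stage: %s", stage),
    sprintf("# config_hash: %s",
            if (is.null(config)) "none" else rlang::hash(config)),
    sprintf("# columns: %s", paste(names(x), collapse = "\t"))
  )
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a pipeline TSV (QuantTable, interaction stats, rewiring calls, ...)
#'
#' Columns are matched by name, so column order is irrelevant; `#` lines are
#' treated as comments.
#'
#' @param path Input path.
#' @return A tibble.
#' @export
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read a replicate-level SILAC QuantTable TSV
#'
#' @param path Input path; must carry the QuantTable columns (`bait`, `prey`,
#'   `condition`, `replicate_id`, `bio_rep`, `tech_rep`,
#'   `label_orientation`, `log2_ratio`).
#' @return A validated tibble.
#' @export
read_quant_table <- function(path) {
  x <- read_stage_tsv(path)
  check_quant_table(x, arg = path)
  x
}

#' Read an effector catalogue (TSV or JSON)
#'
#' TSV columns: `name`, `total_conc_nM`, `kd_nM`, optional `pathway`. JSON:
#' an array of objects with the same fields.
#'
#' @param path Input path ending in `.tsv`/`.txt` or `.json`.
#' @return An [effector_spec()].
#' @export
read_effectors <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    read_stage_tsv(path)
  }
  need <- c("name", "total_conc_nM", "kd_nM")
  if (!all(need %in% names(x))) {
    abort(paste0("effector catalogue needs columns: ",
                 paste(need, collapse = ", ")),
          class = "ppirewire_schema_error")
  }
  effector_spec(x$name, x$total_conc_nM, x$kd_nM,
                pathway = if ("pathway" %in% names(x)) x$pathway
                          else NA_character_)
}

#' Read protein-complex definitions
#'
#' Two-column TSV (`complex`, `member`), one row per membership.
#'
#' @param path Input path.
#' @return A tibble with columns `complex`, `member`.
#' @export
read_complexes <- function(path) {
  x <- read_stage_tsv(path)
  if (!all(c("complex", "member") %in% names(x))) {
    abort("complex definitions need columns `complex`, `member`",
          class = "ppirewire_schema_error")
  }
  x
}

#' Read a prey-prey edge list (TSV or SIF) for network augmentation
#'
#' TSV needs columns `from`, `to`; SIF rows are
#' `source<TAB>interaction<TAB>target...` with one target per extra column.
#'
#' @param path Input path; `.sif` selects the SIF parser.
#' @return Tibble with columns `from`, `to`, `source`.
#' @export
read_edge_list <- function(path) {
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t")
    edges <- purrr::map_dfr(parts, function(p) {
      if (length(p) < 3) return(NULL)
      tibble(from = p[1], to = p[3:length(p)])
    })
    edges$source <- "sif"
    return(edges)
  }
  x <- read_stage_tsv(path)
  if (!all(c("from", "to") %in% names(x))) {
    abort("edge list needs columns `from`, `to`",
          class = "ppirewire_schema_error")
  }
  if (!"source" %in% names(x)) x$source <- "extra"
  x
}

#' Export a network as SIF or GraphML
#'
#' SIF rows are `bait <category-or-pp> prey`; GraphML carries node `type` and
#' all edge attributes for external viewers.
#'
#' @param net An `igraph` network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(net, path) {
  edges <- network_edges(net)
  rel <- if ("category" %in% names(edges)) {
    ifelse(is.na(edges$category), "pp", edges$category)
  } else {
    "pp"
  }
  writeLines(paste(edges$from, rel, edges$to, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_network_graphml <- function(net, path) {
  # graphml cannot hold NA attributes; blank them out
  for (a in igraph::edge_attr_names(net)) {
    v <- igraph::edge_attr(net, a)
    if (anyNA(v)) {
      igraph::edge_attr(net, a) <- if (is.character(v)) {
        if_else(is.na(v), "", v)
      } else {
        if_else(is.na(v), 0, as.numeric(v))
      }
    }
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a topology report as JSON
#'
#' @param report A `topology_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(report, path) {
  jsonlite::write_json(
    list(network = report$network, nodes = report$nodes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
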