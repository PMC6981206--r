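#' Build a spoke-model protein-protein interaction network
#'
#' Connects each bait to its retained preys (undirected; AP-MS gives no edge
#' direction and no prey-prey evidence, so no matrix-model inflation is
#' performed). Duplicate (bait, prey) rows are collapsed to a single edge
#' keeping the attributes of the better P value; self-loops are dropped.
#'
#' @param interactions Tibble of filtered interaction statistics with columns
#'   `bait`, `prey` and optionally `mean_log2fc`, `p_value`.
#' @return An undirected `igraph` graph with vertex attribute `type`
#'   (`bait`, `prey` or `both`) and edge attributes `bait`, `prey`,
#'   `mean_log2fc`, `p_value`, `source`.
#' @export
build_network <- function(interactions) {
  if (nrow(interactions) == 0) {
    warn("no interactions supplied; returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (!all(c("bait", "prey") %in% names(interactions))) {
    abort("interactions need `bait` and `prey` columns",
          class = "ppirewire_schema_error")
  }
  edges <- interactions |>
    filter(.data$bait != .data$prey) |>
    mutate(
      mean_log2fc = if ("mean_log2fc" %in% names(interactions))
        .data$mean_log2fc else NA_real_,
      p_value = if ("p_value" %in% names(interactions))
        .data$p_value else NA_real_
    ) |>
    arrange(.data$p_value) |>
    distinct(.data$bait, .data$prey, .keep_all = TRUE) |>
    select("bait", "prey", "mean_log2fc", "p_value")
  graph_from_ppi_edges(edges, baits = unique(edges$bait), source = "apms")
}

# Construct a typed undirected graph from a bait/prey edge tibble. Extra
# columns become edge attributes; `bait`/`prey` are retained as attributes so
# edge provenance survives igraph vertex reindexing.
graph_from_ppi_edges <- function(edges, baits, extra_nodes = character(0),
                                 source = "apms") {
  nodes <- tibble(name = unique(c(edges$bait, edges$prey, extra_nodes)))
  nodes$type <- dplyr::case_when(
    nodes$name %in% baits & nodes$name %in% edges$prey ~ "both",
    nodes$name %in% baits ~ "bait",
    TRUE ~ "prey"
  )
  edges$source <- if (!"source" %in% names(edges)) source else edges$source
  g <- igraph::graph_from_data_frame(
    edges |> rename(from = "bait", to = "prey"),
    directed = FALSE, vertices = nodes)
  # keep endpoints queryable as plain columns
  igraph::E(g)$bait <- edges$bait
  igraph::E(g)$prey <- edges$prey
  g
}

#' Edge and node tibbles of a PPI network
#'
#' @param net An `igraph` network from [build_network()] or friends.
#' @return A tibble of edges (with all edge attributes) or nodes.
#' @export
network_edges <- function(net) {
  as_tibble(igraph::as_data_frame(net, what = "edges"))
}

#' @rdname network_edges
#' @export
network_nodes <- function(net) {
  as_tibble(igraph::as_data_frame(net, what = "vertices"))
}

#' Merge two condition networks into a differential network
#'
#' Takes the union of the hi and lo edge sets and attaches the rewiring
#' category of every union edge from `calls`. The result carries a graph
#' attribute `category_counts` with the five-way category tally (which
#' partitions the union edge count).
#'
#' @param net_hi,net_lo Condition networks from [build_network()].
#' @param calls Rewiring calls from [classify_rewiring()] covering the union.
#' @return An undirected `igraph` with edge attribute `category`.
#' @export
merge_differential <- function(net_hi, net_lo, calls) {
  e_hi <- network_edges(net_hi) |> select("bait", "prey")
  e_lo <- network_edges(net_lo) |> select("bait", "prey")
  union <- bind_rows(e_hi, e_lo) |> distinct(.data$bait, .data$prey)
  merged <- union |>
    left_join(calls |>
                select("bait", "prey", "category", "log2fc_hi_vs_lo",
                       "diff_p"),
              by = c("bait", "prey"))
  if (anyNA(merged$category)) {
    miss <- merged |> filter(is.na(.data$category))
    abort(paste0("rewiring call missing for edge(s): ",
                 paste(head(paste(miss$bait, miss$prey, sep = "-"), 10),
                       collapse = ", ")),
          class = "ppirewire_coverage_error")
  }
  baits <- unique(c(network_nodes(net_hi) |>
                      filter(.data$type != "prey") |> pull("name"),
                    network_nodes(net_lo) |>
                      filter(.data$type != "prey") |> pull("name")))
  g <- graph_from_ppi_edges(merged, baits = baits, source = "apms")
  counts <- table(factor(merged$category, levels = rewiring_levels()))
  g <- igraph::set_graph_attr(g, "category_counts", as.list(counts))
  g <- igraph::set_graph_attr(g, "differential", TRUE)
  g
}

#' Topology metrics of a PPI network
#'
#' Per-node degree, Brandes betweenness centrality (normalised by
#' `(n-1)(n-2)/2`), and local clustering coefficient (triangle fraction),
#' plus network-level average shortest-path length over the largest
#' component, component count, and a scale-freeness fit: the exponent of
#' `P(k) ~ k^-gamma` by least squares of `log10 P(k)` on `log10 k` over
#' degrees `k >= 1` with nonzero counts (the convention of interactive
#' network-analysis tools), with `method = "mle"` offering the
#' maximum-likelihood alternative.
#'
#' @param net An `igraph` network.
#' @param method Power-law fitting method, `"loglog"` (default) or `"mle"`.
#' @return A list of class `topology_report` with tibble `nodes` and list
#'   `network`.
#' @export
topology_metrics <- function(net, method = c("loglog", "mle")) {
  method <- match.arg(method)
  n <- igraph::vcount(net)
  if (n == 0) abort("empty network", class = "ppirewire_input_error")
  if (n == 1) {
    warn("single-node network; all metrics defined as 0")
    nodes <- tibble(node = igraph::V(net)$name %||% "1", degree = 0,
                    betweenness = 0, clustering = 0)
    return(structure(list(
      nodes = nodes,
      network = list(n_nodes = 1, n_edges = 0, avg_path_length = 0,
                     n_components = 1, powerlaw_exponent = 0,
                     powerlaw_r2 = 0)), class = "topology_report"))
  }
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, normalized = TRUE)
  clu <- igraph::transitivity(net, type = "local", isolates = "zero")
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  apl <- if (igraph::vcount(giant) > 1) {
    igraph::mean_distance(giant, directed = FALSE)
  } else 0

  dd <- table(deg[deg >= 1])
  k <- as.numeric(names(dd))
  pk <- as.numeric(dd) / sum(dd)
  if (method == "mle") {
    fit <- igraph::fit_power_law(deg[deg >= 1], xmin = 1)
    gamma <- fit$alpha
    r2 <- NA_real_
  } else if (length(k) >= 2) {
    lmfit <- stats::lm(log10(pk) ~ log10(k))
    gamma <- -unname(stats::coef(lmfit)[2])
    r2 <- summary(lmfit)$r.squared
  } else {
    warn("fewer than two distinct degrees; power-law fit undefined")
    gamma <- NA_real_
    r2 <- NA_real_
  }

  structure(list(
    nodes = tibble(node = igraph::V(net)$name, degree = as.numeric(deg),
                   betweenness = unname(btw), clustering = unname(clu)),
    network = list(n_nodes = n, n_edges = igraph::ecount(net),
                   avg_path_length = apl, n_components = comp$no,
                   powerlaw_exponent = gamma, powerlaw_r2 = r2)
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report> ", x$network$n_nodes, " nodes, ",
      x$network$n_edges, " edges, ", x$network$n_components,
      " component(s)\n", sep = "")
  cat(sprintf("  avg path length %.3f | power-law exponent %.2f (R2 %.2f)\n",
              x$network$avg_path_length, x$network$powerlaw_exponent,
              x$network$powerlaw_r2))
  invisible(x)
}

#' Rank baits by their number of rewired interactions
#'
#' Counts, for every bait, the incident differential-network edges whose
#' category is not `unchanged` (or, with `hi_enhanced_only`, only edges
#' gained in or shifted towards the hi condition) and returns the top `k`
#' baits by that count. Ties are broken lexicographically by bait identifier
#' for reproducibility.
#'
#' @param diff A differential network from [merge_differential()].
#' @param k Number of top baits to return.
#' @param hi_enhanced_only Count only `hi_only` and `shared_up_hi` edges.
#' @return Tibble with columns `bait`, `n_rewired`, `rank` (dense).
#' @export
rank_baits_by_rewiring <- function(diff, k = 20, hi_enhanced_only = FALSE) {
  edges <- network_edges(diff)
  if (!"category" %in% names(edges)) {
    abort("network has no `category` edge attribute; run merge_differential()",
          class = "ppirewire_input_error")
  }
  counted <- if (hi_enhanced_only) {
    c("hi_only", "shared_up_hi")
  } else {
    setdiff(rewiring_levels(), "unchanged")
  }
  baits <- network_nodes(diff) |>
    filter(.data$type %in% c("bait", "both")) |>
    pull("name")
  tally <- edges |>
    filter(.data$category %in% counted) |>
    count(.data$bait, name = "n_rewired")
  out <- tibble(bait = baits) |>
    left_join(tally, by = "bait") |>
    mutate(n_rewired = if_else(is.na(.data$n_rewired), 0L,
                               as.integer(.data$n_rewired))) |>
    arrange(desc(.data$n_rewired), .data$bait) |>
    mutate(rank = dplyr::dense_rank(desc(.data$n_rewired)))
  if (k > length(baits)) {
    warn(sprintf("k = %d exceeds the %d baits; returning all", k,
                 length(baits)))
    k <- length(baits)
  }
  out |> slice_head(n = k)
}

#' Augment a network with extra edges and nodes for flow analysis
#'
#' Unions user-supplied prey-prey (or any) edges and free-standing nodes into
#' a network, collapsing duplicate edges while merging their provenance tags.
#' Typical use is supplementing a spoke-model AP-MS network with public
#' prey-prey interactions and known pathway members before information-flow
#' scoring.
#'
#' @param net An `igraph` network.
#' @param extra_edges Tibble with columns `from`, `to` and optionally
#'   `source`.
#' @param extra_nodes Character vector of additional node names (may be
#'   disconnected; they are retained).
#' @return The augmented `igraph` network.
#' @export
augment_for_flow <- function(net, extra_edges = NULL, extra_nodes = character(0)) {
  edges <- network_edges(net)
  nodes <- network_nodes(net)
  if (is.null(extra_edges) || nrow(extra_edges) == 0) {
    if (length(extra_nodes) == 0) return(net)
    extra_edges <- tibble(from = character(0), to = character(0))
  }
  known <- union(nodes$name, extra_nodes)
  dangling <- setdiff(unique(c(extra_edges$from, extra_edges$to)), known)
  if (length(dangling) > 0) {
    abort(paste0("extra edges reference unknown node(s): ",
                 paste(head(dangling, 10), collapse = ", ")),
          class = "ppirewire_input_error")
  }
  extra <- extra_edges |>
    mutate(source = if ("source" %in% names(extra_edges))
      .data$source else "extra")
  all_edges <- bind_rows(
    edges |> select(-dplyr::any_of(c("bait", "prey"))) |>
      rename(from = "from", to = "to"),
    extra
  )
  if (!"category" %in% names(all_edges)) all_edges$category <- NA_character_
  if (!"mean_log2fc" %in% names(all_edges)) all_edges$mean_log2fc <- NA_real_
  all_edges <- all_edges |>
    mutate(key = paste(pmin(.data$from, .data$to),
                       pmax(.data$from, .data$to), sep = "\r")) |>
    group_by(.data$key) |>
    summarise(from = .data$from[1], to = .data$to[1],
              mean_log2fc = .data$mean_log2fc[1],
              category = .data$category[1],
              source = paste(unique(.data$source), collapse = "+"),
              .groups = "drop") |>
    select(-"key")
  baits <- nodes |> filter(.data$type %in% c("bait", "both")) |> pull("name")
  g <- graph_from_ppi_edges(
    all_edges |> rename(bait = "from", prey = "to"),
    baits = baits, extra_nodes = union(extra_nodes, nodes$name))
  g
}
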