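#' Flow configuration for information-flow scoring
#'
#' @param source Source node (signal entry point, e.g. a receptor).
#' @param sinks Character vector of absorbing sink nodes (e.g. transcription
#'   factors). Must not contain the source.
#' @param damping Per-step survival probability of the walk in `(0, 1]`;
#'   models signal dissipation. Default 0.85.
#' @return A list of class `flow_config`.
#' @export
flow_config <- function(source, sinks, damping = 0.85) {
  if (length(sinks) == 0) abort("sinks must be non-empty",
                                class = "ppirewire_config_error")
  if (source %in% sinks) abort("source must not be a sink",
                               class = "ppirewire_config_error")
  if (damping <= 0 || damping > 1) abort("damping must be in (0, 1]",
                                         class = "ppirewire_config_error")
  structure(list(source = source, sinks = unique(sinks), damping = damping),
            class = "flow_config")
}

# Row-stochastic transition matrix of an undirected graph (uniform over
# neighbours, or proportional to an edge weight attribute).
transition_matrix <- function(net, weight_attr = NULL) {
  a <- igraph::as_adjacency_matrix(
    net, sparse = FALSE,
    attr = weight_attr)
  deg <- rowSums(a)
  p <- a
  nz <- deg > 0
  p[nz, ] <- a[nz, , drop = FALSE] / deg[nz]
  p
}

#' Channel-model information-flow scores
#'
#' Scores every node by the expected number of visits of a damped discrete-
#' time random walk started at `source`, conditioned on absorption at one of
#' the `sinks` before dissipation. With `P` the row-stochastic transition
#' operator, `d` the damping factor and `Q = d * P` restricted to transient
#' (non-sink) nodes, unconditioned expected visits are the source row of
#' `(I - Q)^{-1}`; the absorption probability `h` solves
#' `h = d * (P_toSinks 1 + P_transient h)`; the conditioned score of a
#' transient node `v` is `visits(s, v) * h(v) / h(s)`, and each sink's score
#' is its share of the conditioned absorption mass. Initial placement at the
#' source counts as one visit, so the source score is at least 1. Scores are
#' also returned normalised to the node's share of total network flow, which
#' makes networks of different size comparable.
#'
#' @param net An `igraph` network.
#' @param cfg A [flow_config()].
#' @param weight_attr Optional edge attribute to weight transitions
#'   (default unweighted).
#' @return A tibble of class `ifs_table`: `node`, `role` (`source`,
#'   `transient`, `sink`), `ifs`, `ifs_norm` (sums to 1), `absorption`
#'   (sinks only: conditioned absorption probability; sums to 1 over sinks).
#' @export
ifs_scores <- function(net, cfg, weight_attr = NULL) {
  stopifnot(inherits(cfg, "flow_config"))
  nodes <- igraph::V(net)$name
  missing <- setdiff(c(cfg$source, cfg$sinks), nodes)
  if (length(missing) > 0) {
    abort(paste0("node(s) absent from the network: ",
                 paste(missing, collapse = ", ")),
          class = "ppirewire_input_error")
  }
  dist_to_sinks <- igraph::distances(net, v = cfg$source, to = cfg$sinks)
  unreachable <- cfg$sinks[!is.finite(dist_to_sinks[1, ])]
  if (length(unreachable) > 0) {
    abort(paste0("sink(s) unreachable from the source: ",
                 paste(unreachable, collapse = ", ")),
          class = "ppirewire_input_error")
  }

  p <- transition_matrix(net, weight_attr)
  sink_idx <- match(cfg$sinks, nodes)
  trans_idx <- setdiff(seq_along(nodes), sink_idx)
  s_pos <- match(cfg$source, nodes[trans_idx])
  d <- cfg$damping

  q <- d * p[trans_idx, trans_idx, drop = FALSE]
  r <- d * p[trans_idx, sink_idx, drop = FALSE]
  m <- diag(length(trans_idx)) - q

  solve_or_fail <- function(a, b) {
    tryCatch(solve(a, b), error = function(e) {
      abort(paste0("singular linear system in flow computation (",
                   conditionMessage(e), ")"),
            class = "ppirewire_solver_error")
    })
  }
  e_s <- numeric(length(trans_idx))
  e_s[s_pos] <- 1
  visits <- drop(solve_or_fail(t(m), e_s))       # row s of (I - Q)^{-1}
  h <- drop(solve_or_fail(m, rowSums(r)))        # absorption probability
  if (h[s_pos] <= 0) {
    abort("source cannot reach any sink under the damped walk",
          class = "ppirewire_input_error")
  }
  ifs_trans <- visits * h / h[s_pos]
  absorption <- drop(crossprod(visits, r)) / h[s_pos]  # per-sink split

  out <- tibble(
    node = c(nodes[trans_idx], nodes[sink_idx]),
    role = c(if_else(nodes[trans_idx] == cfg$source, "source", "transient"),
             rep("sink", length(sink_idx))),
    ifs = unname(c(ifs_trans, absorption)),
    absorption = unname(c(rep(NA_real_, length(trans_idx)), absorption))
  )
  out$ifs_norm <- out$ifs / sum(out$ifs)
  out <- structure(out, class = c("ifs_table", class(tibble())))
  attr(out, "config") <- cfg
  out
}

#' Monte-Carlo reference for channel-model scores
#'
#' Simulates damped random walks from the source and tabulates visit counts
#' of walks that reach a sink, giving an independent stochastic estimate of
#' the conditioned scores of [ifs_scores()]. Used as a correctness standard
#' in testing; also useful for intuition on small graphs.
#'
#' @inheritParams ifs_scores
#' @param n_walks Number of simulated walks.
#' @param seed Integer seed.
#' @return A tibble: `node`, `ifs_mc` (conditioned visit estimate; for sinks,
#'   the conditioned absorption share), `n_absorbed`.
#' @export
simulate_damped_walks <- function(net, cfg, n_walks = 1e5, seed = 1L) {
  stopifnot(inherits(cfg, "flow_config"))
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  adj <- igraph::as_adj_list(net)
  neigh <- lapply(adj, as.integer)
  deg <- lengths(neigh)
  flat <- unlist(neigh)
  offset <- c(0L, cumsum(deg))
  sink_idx <- match(cfg$sinks, nodes)
  is_sink <- rep(FALSE, n)
  is_sink[sink_idx] <- TRUE
  s_idx <- match(cfg$source, nodes)
  d <- cfg$damping

  local_seed(seed, {
    state <- rep.int(s_idx, n_walks)
    walker <- seq_len(n_walks)
    end_state <- integer(n_walks)        # 0 = dissipated
    ev_walker <- vector("list", 0)
    ev_node <- vector("list", 0)
    step <- 0L
    while (length(walker) > 0) {
      step <- step + 1L
      ev_walker[[step]] <- walker
      ev_node[[step]] <- state
      survive <- stats::runif(length(walker)) < d
      dead_end <- deg[state] == 0L
      keep <- survive & !dead_end
      walker <- walker[keep]
      state <- state[keep]
      if (length(walker) == 0) break
      pick <- offset[state] + sample.int(.Machine$integer.max,
                                         length(state)) %% deg[state] + 1L
      state <- flat[pick]
      hit <- is_sink[state]
      end_state[walker[hit]] <- state[hit]
      walker <- walker[!hit]
      state <- state[!hit]
    }
    absorbed <- end_state > 0L
    n_abs <- sum(absorbed)
    if (n_abs == 0) {
      abort("no simulated walk reached a sink; increase n_walks or damping",
            class = "ppirewire_solver_error")
    }
    w <- unlist(ev_walker)
    v <- unlist(ev_node)
    keep <- absorbed[w]
    visit_counts <- tabulate(v[keep], nbins = n)
    sink_counts <- tabulate(end_state[absorbed], nbins = n)
    tibble(
      node = nodes,
      ifs_mc = if_else(is_sink, sink_counts / n_abs, visit_counts / n_abs),
      n_absorbed = n_abs
    )
  })
}

#' Differential information flow between two condition networks
#'
#' Compares normalised scores node by node. Nodes present in both networks
#' whose share-of-flow ratio exceeds `node_fold` in either direction are
#' flagged; sink nodes are additionally flagged at the gentler `tf_fold`
#' threshold. Nodes present in only one network are listed separately as
#' exclusive rather than folded.
#'
#' @param table_hi,table_lo [ifs_scores()] tables of the two networks.
#' @param node_fold Fold threshold for any node (default 2: a >2-fold
#'   difference in share of flow).
#' @param tf_fold Fold threshold for sinks (default 1.2: at least 20% higher
#'   flow).
#' @return A list of class `ifs_diff`: `shared` tibble (`node`, `role`,
#'   `ifs_norm_hi`, `ifs_norm_lo`, `ratio_hi_vs_lo`, `direction`,
#'   `node_flag`, `tf_flag`, `infinite_ratio`), `exclusive` tibble (`node`,
#'   `present_in`), and the thresholds.
#' @export
differential_ifs <- function(table_hi, table_lo, node_fold = 2.0,
                             tf_fold = 1.2) {
  shared <- inner_join(
    table_hi |> select("node", "role", ifs_norm_hi = "ifs_norm"),
    table_lo |> select("node", ifs_norm_lo = "ifs_norm"),
    by = "node")
  shared <- shared |>
    mutate(
      infinite_ratio = .data$ifs_norm_lo == 0 & .data$ifs_norm_hi > 0,
      ratio_hi_vs_lo = if_else(.data$infinite_ratio, Inf,
                               .data$ifs_norm_hi / .data$ifs_norm_lo),
      fold = pmax(.data$ratio_hi_vs_lo, 1 / .data$ratio_hi_vs_lo),
      direction = dplyr::case_when(
        .data$ratio_hi_vs_lo > 1 ~ "up_hi",
        .data$ratio_hi_vs_lo < 1 ~ "up_lo",
        TRUE ~ "equal"),
      node_flag = .data$fold > node_fold,
      tf_flag = .data$role == "sink" & .data$fold >= tf_fold
    ) |>
    select(-"fold")
  exclusive <- bind_rows(
    anti_join(table_hi, table_lo, by = "node") |>
      select("node") |> mutate(present_in = "hi"),
    anti_join(table_lo, table_hi, by = "node") |>
      select("node") |> mutate(present_in = "lo")
  )
  structure(list(shared = shared, exclusive = exclusive,
                 node_fold = node_fold, tf_fold = tf_fold),
            class = "ifs_diff")
}

#' @export
print.ifs_diff <- function(x, ...) {
  cat("<ifs_diff> ", sum(x$shared$node_flag), " node(s) beyond ",
      x$node_fold, "-fold, ", sum(x$shared$tf_flag), " sink(s) beyond ",
      x$tf_fold, "-fold, ", nrow(x$exclusive), " exclusive\n", sep = "")
  invisible(x)
}
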