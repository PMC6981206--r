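stats_tbl <- function(bait, prey, p = 0.01, fc = 2) {
  tibble::tibble(bait = bait, prey = prey, p_value = p, mean_log2fc = fc,
                 sig_a = 0.01)
}

test_that("spoke-model construction counts nodes and edges correctly", {
  net <- build_network(stats_tbl(c("B1", "B2"), c("P1", "P1")))
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)
  types <- network_nodes(net)
  expect_setequal(types$type[types$name %in% c("B1", "B2")], "bait")

  # duplicate rows collapse, keeping the better P value
  dup <- dplyr::bind_rows(stats_tbl("B1", "P1", p = 0.04, fc = 1),
                          stats_tbl("B1", "P1", p = 0.001, fc = 3))
  net2 <- build_network(dup)
  expect_equal(igraph::ecount(net2), 1)
  expect_equal(network_edges(net2)$p_value, 0.001)
  expect_equal(network_edges(net2)$mean_log2fc, 3)

  expect_warning(empty <- build_network(stats_tbl(character(0), character(0))),
                 "no interactions")
  expect_equal(igraph::vcount(empty), 0)

  # edge count conserved from retained interactions
  many <- stats_tbl(rep(sprintf("B%d", 1:5), each = 10),
                    sprintf("P%02d", c(replicate(5, sample(30, 10)))))
  many <- dplyr::distinct(many, bait, prey, .keep_all = TRUE)
  expect_equal(igraph::ecount(build_network(many)), nrow(many))
})

test_that("differential merge attaches categories that partition the union", {
  hi <- build_network(stats_tbl(c("B1", "B1", "B2"), c("P1", "P2", "P3")))
  lo <- build_network(stats_tbl(c("B1", "B2", "B2"), c("P1", "P3", "P4")))
  calls <- tibble::tibble(
    bait = c("B1", "B1", "B2", "B2"),
    prey = c("P1", "P2", "P3", "P4"),
    category = c("unchanged", "hi_only", "shared_up_lo", "lo_only"),
    log2fc_hi_vs_lo = c(0, 4, -1.5, -4),
    diff_p = c(0.9, 0.001, 0.01, 0.001))
  dn <- merge_differential(hi, lo, calls)
  expect_equal(igraph::ecount(dn), 4)
  counts <- igraph::graph_attr(dn, "category_counts")
  expect_equal(sum(unlist(counts)), igraph::ecount(dn))
  expect_equal(counts$hi_only, 1)

  # identical networks, all unchanged: zero rewired
  same <- merge_differential(hi, hi, tibble::tibble(
    bait = c("B1", "B1", "B2"), prey = c("P1", "P2", "P3"),
    category = "unchanged", log2fc_hi_vs_lo = 0, diff_p = 1))
  expect_equal(igraph::graph_attr(same, "category_counts")$unchanged, 3)

  # a union edge without a call is an error
  expect_error(merge_differential(hi, lo, calls[-1, ]),
               class = "ppirewire_coverage_error")
})

test_that("topology metrics are exact on canonical small graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  rep_tri <- suppressWarnings(topology_metrics(tri))
  expect_equal(rep_tri$nodes$clustering, rep(1, 3))
  expect_equal(rep_tri$nodes$betweenness, rep(0, 3))

  path3 <- igraph::make_graph(~ a - b, b - c)
  rep_p <- suppressWarnings(topology_metrics(path3))
  expect_equal(rep_p$nodes$betweenness[rep_p$nodes$node == "b"], 1)

  star <- igraph::make_star(11, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", sprintf("l%d", 1:10))
  rep_s <- suppressWarnings(topology_metrics(star))
  hub <- rep_s$nodes[rep_s$nodes$node == "hub", ]
  expect_equal(hub$degree, 10)
  expect_equal(hub$betweenness, 1)
  expect_equal(rep_s$nodes$clustering[rep_s$nodes$node != "hub"], rep(0, 10))
  expect_equal(rep_s$network$n_components, 1)
  expect_equal(rep_s$network$avg_path_length, (10 * 1 + 45 * 2) / 55)
})

test_that("betweenness and path length agree with brute-force enumeration", {
  for (seed in 1:6) {
    g <- random_named_graph(sample(5:8, 1), p = 0.4, seed = seed)
    rep <- suppressWarnings(topology_metrics(g))
    expect_equal(rep$nodes$betweenness, brute_betweenness(g),
                 tolerance = 1e-10)
    expect_equal(rep$network$avg_path_length, brute_avg_path(g),
                 tolerance = 1e-10)
  }
})

test_that("single-node networks degrade gracefully", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "solo"
  expect_warning(rep1 <- topology_metrics(g1), "single-node")
  expect_equal(rep1$network$avg_path_length, 0)
})

test_that("bait ranking counts rewired incident edges with stable ties", {
  hi <- build_network(stats_tbl(rep(c("A", "B", "C"), each = 3),
                                sprintf("P%d", 1:9)))
  calls <- tibble::tibble(
    bait = rep(c("A", "B", "C"), each = 3),
    prey = sprintf("P%d", 1:9),
    category = c("hi_only", "hi_only", "shared_up_hi",   # A: 3 rewired
                 "lo_only", "unchanged", "unchanged",    # B: 1
                 "unchanged", "unchanged", "unchanged"), # C: 0
    log2fc_hi_vs_lo = 0, diff_p = 0.01)
  dn <- merge_differential(hi, hi, calls)
  rk <- rank_baits_by_rewiring(dn, k = 3)
  expect_equal(rk$bait, c("A", "B", "C"))
  expect_equal(rk$n_rewired, c(3L, 1L, 0L))

  # hi-enhanced mode only counts gains/up-shifts
  rk_hi <- rank_baits_by_rewiring(dn, k = 3, hi_enhanced_only = TRUE)
  expect_equal(rk_hi$n_rewired[rk_hi$bait == "B"], 0L)

  # no rewired edges: all zero, lexicographic order
  none <- calls |> dplyr::mutate(category = "unchanged")
  rk0 <- rank_baits_by_rewiring(merge_differential(hi, hi, none), k = 3)
  expect_equal(rk0$bait, c("A", "B", "C"))
  expect_true(all(rk0$n_rewired == 0))

  expect_warning(rank_baits_by_rewiring(dn, k = 10), "exceeds")
})

test_that("augmentation unions edges, merges provenance, and checks endpoints", {
  net <- build_network(stats_tbl(c("B1", "B1"), c("P1", "P2")))
  expect_identical(augment_for_flow(net), net)

  # duplicate edge: count unchanged, provenance merged
  aug <- augment_for_flow(net, tibble::tibble(from = "B1", to = "P1"))
  expect_equal(igraph::ecount(aug), 2)
  e <- network_edges(aug)
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_true("apms+extra" %in% e$source[key == paste("B1", "P1")])

  # a prey-prey edge closes a triangle and raises clustering
  before <- suppressWarnings(topology_metrics(net))$nodes
  aug2 <- augment_for_flow(net, tibble::tibble(from = "P1", to = "P2"))
  after <- suppressWarnings(topology_metrics(aug2))$nodes
  expect_gt(after$clustering[after$node == "B1"],
            before$clustering[before$node == "B1"])

  # disconnected extra nodes are retained
  aug3 <- augment_for_flow(net, extra_nodes = "LONER")
  expect_true("LONER" %in% igraph::V(aug3)$name)

  expect_error(augment_for_flow(net, tibble::tibble(from = "B1", to = "GHOST")),
               class = "ppirewire_input_error")
})
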