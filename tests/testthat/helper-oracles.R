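# Independent brute-force oracles used to check the package's fast paths.

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# background of N in which K elements are "focal" and count draws whose
# focal overlap is at least k.
brute_hypergeom_upper <- function(N, n, K, k) {
  draws <- utils::combn(N, n)
  focal <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% focal) >= k)
  mean(hits)
}

# Brute-force betweenness: enumerate all simple paths between every node
# pair by depth-first search, keep the shortest, and accumulate each interior
# node's share of shortest paths. Normalised by (n-1)(n-2)/2 (undirected).
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    out
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        btw[interior] <- btw[interior] + 1 / length(shortest)
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# Brute-force average shortest-path length over the largest component via
# breadth-first search from every node.
brute_avg_path <- function(g) {
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  d <- igraph::distances(sub)
  mean(d[upper.tri(d)])
}

# Spearman rho from first principles (no ties expected).
brute_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# One-effector competition closed form: bound complex concentration is the
# smaller root of C^2 - (R + E + Kd) C + R E = 0.
one_effector_complex <- function(r_total, e_total, kd) {
  b <- r_total + e_total + kd
  (b - sqrt(b^2 - 4 * r_total * e_total)) / 2
}

# Small QuantTable builder for hand-crafted replicate sets.
quant_rows <- function(bait, prey, values, condition = "hi",
                       orientation = "forward") {
  tibble::tibble(
    bait = bait, prey = prey, condition = condition,
    replicate_id = sprintf("b%dt1", seq_along(values)),
    bio_rep = seq_along(values), tech_rep = 1L,
    label_orientation = orientation, log2_ratio = values
  )
}

# A small connected random graph with named nodes.
random_named_graph <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}
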