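#' Tidy a competition-model result
#'
#' @param x A `competition_result` from [solve_equilibrium()].
#' @param ... Unused.
#' @return One row per effector: concentrations, bound fraction and affinity
#'   class at the solved equilibrium.
#' @method tidy competition_result
#' @export
tidy.competition_result <- function(x, ...) {
  x$effectors
}

#' @rdname tidy.competition_result
#' @return For `glance()`: a one-row tibble with `r_total`, `r_free`,
#'   `bound_total`, `residual`, `iterations`, `n_effectors`.
#' @method glance competition_result
#' @export
glance.competition_result <- function(x, ...) {
  tibble(r_total = x$r_total, r_free = x$r_free,
         bound_total = x$r_total - x$r_free,
         residual = x$residual, iterations = x$iterations,
         n_effectors = nrow(x$effectors))
}

#' Tidy a truth network
#'
#' @param x A `truth_network`.
#' @param ... Unused.
#' @return The edge tibble (bait, prey, category, effect_size, presence).
#' @method tidy truth_network
#' @export
tidy.truth_network <- function(x, ...) {
  x$edges
}

#' @rdname tidy.truth_network
#' @method glance truth_network
#' @export
glance.truth_network <- function(x, ...) {
  cts <- table(factor(x$edges$category, levels = rewiring_levels()))
  tibble(n_baits = length(x$baits), n_edges = nrow(x$edges),
         n_preys = length(unique(x$edges$prey)),
         n_hi_only = unname(cts[["hi_only"]]),
         n_lo_only = unname(cts[["lo_only"]]),
         n_shifted = unname(cts[["shared_up_hi"]] + cts[["shared_up_lo"]]),
         n_unchanged = unname(cts[["unchanged"]]),
         seed = x$config$seed)
}

#' Tidy a topology report
#'
#' @param x A `topology_report`.
#' @param ... Unused.
#' @return Per-node metric tibble; `glance()` gives the network-level row.
#' @method tidy topology_report
#' @export
tidy.topology_report <- function(x, ...) {
  x$nodes
}

#' @rdname tidy.topology_report
#' @method glance topology_report
#' @export
glance.topology_report <- function(x, ...) {
  as_tibble(x$network)
}

#' Tidy a differential information-flow report
#'
#' @param x An `ifs_diff`.
#' @param ... Unused.
#' @return The shared-node comparison tibble; `glance()` summarises flag
#'   counts.
#' @method tidy ifs_diff
#' @export
tidy.ifs_diff <- function(x, ...) {
  x$shared
}

#' @rdname tidy.ifs_diff
#' @method glance ifs_diff
#' @export
glance.ifs_diff <- function(x, ...) {
  tibble(n_shared = nrow(x$shared),
         n_node_flagged = sum(x$shared$node_flag),
         n_tf_flagged = sum(x$shared$tf_flag),
         n_exclusive = nrow(x$exclusive),
         node_fold = x$node_fold, tf_fold = x$tf_fold)
}

#' Tidy a pipeline report
#'
#' @param x A `pipeline_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The rewiring-call tibble; `glance()` gives the headline counts as
#'   one row.
#' @method tidy pipeline_report
#' @export
tidy.pipeline_report <- function(x, ...) {
  x$calls
}

#' @rdname tidy.pipeline_report
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  s <- x$summary
  tibble(
    n_baits = s$n_baits,
    hi_edges = s$network$hi$edges, lo_edges = s$network$lo$edges,
    union_edges = s$network$union_edges, n_rewired = s$n_rewired,
    hi_only = s$rewiring$hi_only, lo_only = s$rewiring$lo_only,
    shared_up_hi = s$rewiring$shared_up_hi,
    shared_up_lo = s$rewiring$shared_up_lo,
    n_ifs_node_flagged = s$flow$n_node_flagged,
    seed = s$seed
  )
}
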