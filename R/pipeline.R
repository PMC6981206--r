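#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Data enter either as paths to
#' QuantTable TSVs (`pulldown`, `control`, `hi_vs_lo`) or as a simulation
#' config — exactly one of the two.
#'
#' @param simulation A [sim_config()] (synthetic mode), or `NULL`.
#' @param input Named list of paths (`pulldown`, `control`, `hi_vs_lo`), or
#'   `NULL`.
#' @param thresholds A [ppi_thresholds()].
#' @param flow `NULL` for automatic source/sink selection, or a list with
#'   `source`, `sinks`, `damping` (see [flow_config()]); with `n_sinks`, the
#'   automatic selection picks that many sink nodes (default 19).
#' @param effectors An [effector_spec()] or path readable by
#'   [read_effectors()], or `NULL` to skip the competition stage.
#' @param pathway_map Tibble (`bait`, `pathway`) or path, or `NULL`.
#' @param protein_tables List passed to [simulate_protein_tables()]
#'   (`n_de`, `n_dp`, `overlap_with_rewired`, `n_universe`) or named list of
#'   paths (`abundance`, `phospho`), or `NULL` to skip enrichment.
#' @param complexes Complex definitions tibble or path, or `NULL`.
#' @param r_lo,r_hi Active-GTPase doses (nM) for the competition stage.
#' @param out_dir Output directory for stage files, or `NULL` to skip
#'   writing.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param quiet Suppress per-stage messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            input = NULL,
                            thresholds = ppi_thresholds(),
                            flow = NULL,
                            effectors = default_effectors(),
                            pathway_map = NULL,
                            protein_tables = list(),
                            complexes = NULL,
                            r_lo = 150, r_hi = 400,
                            out_dir = NULL,
                            seed = NULL,
                            quiet = FALSE) {
  if (is.null(simulation) == is.null(input)) {
    abort("provide exactly one of `simulation` or `input`",
          class = "ppirewire_config_error")
  }
  if (!is.null(seed) && !is.null(simulation)) {
    simulation$seed <- as.integer(seed)
  }
  structure(list(
    simulation = simulation, input = input, thresholds = thresholds,
    flow = flow, effectors = effectors, pathway_map = pathway_map,
    protein_tables = protein_tables, complexes = complexes,
    r_lo = r_lo, r_hi = r_hi, out_dir = out_dir,
    seed = seed %||% (if (!is.null(simulation)) simulation$seed else 1L),
    quiet = quiet
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `simulation` holds [sim_config()] fields, `thresholds` holds
#' [ppi_thresholds()] fields, and `effectors`, `pathway_map`, `complexes`
#' may be file paths.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(sim_config, y$simulation)
  thr <- if (!is.null(y$thresholds)) {
    do.call(ppi_thresholds, y$thresholds)
  } else {
    ppi_thresholds()
  }
  eff <- if (is.character(y$effectors)) {
    read_effectors(y$effectors)
  } else if (!is.null(y$effectors)) {
    do.call(effector_spec, y$effectors)
  } else {
    default_effectors()
  }
  pmap_tbl <- if (is.character(y$pathway_map)) {
    read_stage_tsv(y$pathway_map)
  } else if (!is.null(y$pathway_map)) {
    as_tibble(y$pathway_map)
  }
  cplx <- if (is.character(y$complexes)) read_complexes(y$complexes)
  pipeline_config(
    simulation = sim, input = y$input, thresholds = thr, flow = y$flow,
    effectors = eff, pathway_map = pmap_tbl,
    protein_tables = y$protein_tables %||% list(), complexes = cplx,
    r_lo = y$r_lo %||% 150, r_hi = y$r_hi %||% 400,
    out_dir = y$out_dir, seed = y$seed, quiet = isTRUE(y$quiet))
}

#' Default effector catalogue
#'
#' Illustrative catalogue of seven effector pathways spanning the high- and
#' low-affinity regimes around cellular active-GTPase abundances of a few
#' hundred nM. Concentrations and Kd values are placeholders meant to be
#' replaced by a user-supplied catalogue; nothing downstream depends on
#' these numbers beyond their orders of magnitude.
#'
#' @return An [effector_spec()].
#' @export
default_effectors <- function() {
  effector_spec(
    name = c("RAF", "RAL", "PI3K", "TIAM", "AFDN", "PLCE", "RIN1"),
    total_conc = c(300, 200, 150, 100, 120, 80, 90),
    kd = c(50, 1500, 300, 4000, 2500, 8000, 120),
    pathway = c("RAF/MAPK", "RAL", "PI3K", "TIAM", "AFDN", "PLCE", "RIN1")
  )
}

# Pick a flow source and sinks automatically: the best-connected bait shared
# by both networks as source, and the `n_sinks` highest-degree non-bait nodes
# reachable from it in both networks as sinks.
auto_flow_config <- function(net_hi, net_lo, n_sinks = 19, damping = 0.85) {
  shared <- intersect(igraph::V(net_hi)$name, igraph::V(net_lo)$name)
  deg <- igraph::degree(net_hi)[shared] + igraph::degree(net_lo)[shared]
  types <- network_nodes(net_hi)
  baits <- types$name[types$type %in% c("bait", "both")]
  cand_src <- intersect(names(sort(deg, decreasing = TRUE)), baits)
  if (length(cand_src) == 0) {
    abort("no bait shared by both networks; cannot pick a flow source",
          class = "ppirewire_input_error")
  }
  source <- cand_src[1]
  reach_hi <- igraph::subcomponent(net_hi, source)$name
  reach_lo <- igraph::subcomponent(net_lo, source)$name
  cand_sink <- setdiff(intersect(reach_hi, reach_lo), baits)
  cand_sink <- setdiff(cand_sink, source)
  cand_sink <- cand_sink[order(-deg[cand_sink])]
  if (length(cand_sink) == 0) {
    abort("no shared reachable sink candidates",
          class = "ppirewire_input_error")
  }
  flow_config(source, head(cand_sink, n_sinks), damping = damping)
}

#' Run the differential-interactome pipeline end to end
#'
#' Stages: simulate (or read) replicate tables -> normalise -> enrichment
#' tests vs empty-vector controls -> significance-A -> two-step interactor
#' filter -> condition networks -> direct hi-vs-lo comparison -> rewiring
#' classification -> differential network -> topology -> bait ranking ->
#' effector competition model -> information flow -> differential-set
#' enrichment. Every stage logs input/output row counts; the result carries
#' a machine-readable `summary`. Reruns with the same config and seed are
#' bit-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_report` with all stage outputs and a
#'   `summary` list (written to `out_dir/summary.json` when `out_dir` is
#'   set).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!cfg$quiet) inform(sprintf(...))
  t0 <- Sys.time()

  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    truth <- generate_truth_network(cfg$simulation)
    sim <- simulate_silac_experiment(truth, cfg$simulation)
    say("simulate: %d baits, %d union edges, %d pulldown rows",
        length(truth$baits), nrow(truth$edges), nrow(sim$pulldown))
    tables <- sim
  } else {
    tables <- list(pulldown = read_quant_table(cfg$input$pulldown),
                   control = read_quant_table(cfg$input$control),
                   hi_vs_lo = read_quant_table(cfg$input$hi_vs_lo))
    truth <- NULL
    say("read: %d pulldown, %d control, %d hi-vs-lo rows",
        nrow(tables$pulldown), nrow(tables$control), nrow(tables$hi_vs_lo))
  }

  # --- scoring ------------------------------------------------------------
  pulldown <- normalize_ratios(tables$pulldown)
  control <- normalize_ratios(tables$control)
  hi_vs_lo <- normalize_ratios(tables$hi_vs_lo)
  say("normalize: label-swap corrected, per-run median-centred")

  enrich <- suppressWarnings(test_enrichment(pulldown, control)) |>
    add_significance_a()
  say("enrichment tests: %d (bait, condition, prey) stats", nrow(enrich))

  bait_count <- length(unique(pulldown$bait))
  retained <- enrich |>
    group_by(.data$condition) |>
    dplyr::group_map(~ filter_true_interactors(
      .x |> mutate(condition = .y$condition),
      cfg$thresholds, bait_count = bait_count, quiet = cfg$quiet))
  names(retained) <- sort(unique(enrich$condition))

  net_hi <- build_network(retained[["hi"]])
  net_lo <- build_network(retained[["lo"]])
  say("networks: hi %d nodes / %d edges, lo %d nodes / %d edges",
      igraph::vcount(net_hi), igraph::ecount(net_hi),
      igraph::vcount(net_lo), igraph::ecount(net_lo))

  diff_stats <- suppressWarnings(compare_conditions(hi_vs_lo))
  calls <- classify_rewiring(network_edges(net_hi) |>
                               select(bait = "bait", prey = "prey"),
                             network_edges(net_lo) |>
                               select(bait = "bait", prey = "prey"),
                             diff_stats, cfg$thresholds)
  cat_counts <- as.list(table(factor(calls$category,
                                     levels = rewiring_levels())))
  say("rewiring: %s",
      paste(names(cat_counts), unlist(cat_counts), sep = "=",
            collapse = ", "))

  diff_net <- merge_differential(net_hi, net_lo, calls)
  topo_hi <- topology_metrics(net_hi)
  topo_lo <- topology_metrics(net_lo)
  top_baits <- rank_baits_by_rewiring(diff_net, k = min(20, bait_count))

  # --- competition --------------------------------------------------------
  competition <- NULL
  agreement <- NULL
  if (!is.null(cfg$effectors)) {
    eff <- if (is.character(cfg$effectors)) {
      read_effectors(cfg$effectors)
    } else {
      cfg$effectors
    }
    competition <- dose_fold_change(eff, r_lo = cfg$r_lo, r_hi = cfg$r_hi)
    say("competition: %d effectors, max bound-fraction fold-change %.2f",
        nrow(competition), max(competition$fold_change))
    if (!is.null(cfg$pathway_map)) {
      sens <- suppressWarnings(
        sensitivity_from_apms(diff_stats, cfg$pathway_map))
      if (nrow(sens) >= 3) {
        agreement <- rank_agreement(competition, sens)
        agreement$sensitivity <- sens
        say("model-vs-AP-MS rank agreement: rho = %.2f over %d pathways",
            agreement$rho, agreement$n)
      }
    }
  }

  # --- information flow ---------------------------------------------------
  fc <- if (is.null(cfg$flow)) {
    auto_flow_config(net_hi, net_lo)
  } else if (inherits(cfg$flow, "flow_config")) {
    cfg$flow
  } else {
    flow_config(cfg$flow$source, cfg$flow$sinks,
                damping = cfg$flow$damping %||% 0.85)
  }
  ifs_hi <- ifs_scores(net_hi, fc)
  ifs_lo <- ifs_scores(net_lo, fc)
  ifs_diff <- differential_ifs(ifs_hi, ifs_lo)
  say("information flow: %d node(s) >%.0f-fold, %d sink(s) >=%.0f%% shifted",
      sum(ifs_diff$shared$node_flag), ifs_diff$node_fold,
      sum(ifs_diff$shared$tf_flag), (ifs_diff$tf_fold - 1) * 100)

  # --- enrichment ---------------------------------------------------------
  enrichment <- NULL
  coverage <- NULL
  if (!is.null(cfg$protein_tables) && !is.null(truth)) {
    pt_args <- cfg$protein_tables
    prot <- do.call(simulate_protein_tables,
                    c(list(truth = truth), pt_args))
    rewired_preys <- unique(calls$prey[calls$category != "unchanged"])
    net_nodes <- unique(c(igraph::V(net_hi)$name, igraph::V(net_lo)$name))
    enrichment <- bind_rows(
      set_enrichment(prot$abundance$protein,
                     prot$abundance$protein[prot$abundance$significant],
                     intersect(net_nodes, prot$abundance$protein)) |>
        mutate(test = "DE_in_network", .before = 1),
      set_enrichment(prot$abundance$protein,
                     prot$abundance$protein[prot$abundance$significant],
                     intersect(rewired_preys, prot$abundance$protein)) |>
        mutate(test = "DE_in_rewired", .before = 1),
      set_enrichment(prot$phospho$protein,
                     prot$phospho$protein[prot$phospho$significant],
                     intersect(rewired_preys, prot$phospho$protein)) |>
        mutate(test = "DP_in_rewired", .before = 1)
    )
    say("enrichment: %s",
        paste(enrichment$test, signif(enrichment$p_value, 3),
              sep = " p=", collapse = ", "))
    if (!is.null(cfg$complexes)) {
      coverage <- complex_coverage(cfg$complexes, diff_net, rewired_preys)
    }
  }

  summary <- list(
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "quiet")]),
    n_baits = bait_count,
    network = list(
      hi = list(nodes = igraph::vcount(net_hi),
                edges = igraph::ecount(net_hi)),
      lo = list(nodes = igraph::vcount(net_lo),
                edges = igraph::ecount(net_lo)),
      union_edges = igraph::ecount(diff_net)
    ),
    rewiring = cat_counts,
    n_rewired = sum(calls$category != "unchanged"),
    top_baits = top_baits |> head(5) |> as.list(),
    flow = list(source = fc$source, n_sinks = length(fc$sinks),
                damping = fc$damping,
                n_node_flagged = sum(ifs_diff$shared$node_flag),
                n_tf_flagged = sum(ifs_diff$shared$tf_flag)),
    competition = if (!is.null(competition)) {
      list(max_fold_change = max(competition$fold_change),
           rho = if (!is.null(agreement)) agreement$rho else NA)
    },
    enrichment = if (!is.null(enrichment)) {
      setNames(as.list(enrichment$p_value), enrichment$test)
    },
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  report <- structure(list(
    truth = truth, tables = tables,
    interaction_stats = enrich, retained = retained,
    net_hi = net_hi, net_lo = net_lo,
    diff_stats = diff_stats, calls = calls, diff_net = diff_net,
    topology = list(hi = topo_hi, lo = topo_lo),
    top_baits = top_baits,
    competition = competition, agreement = agreement,
    flow = list(config = fc, hi = ifs_hi, lo = ifs_lo, diff = ifs_diff),
    enrichment = enrichment, complex_coverage = coverage,
    summary = summary, config = cfg
  ), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report> seed ", s$seed, "\n", sep = "")
  cat(sprintf("  networks: hi %d/%d, lo %d/%d, union %d edges\n",
              s$network$hi$nodes, s$network$hi$edges,
              s$network$lo$nodes, s$network$lo$edges, s$network$union_edges))
  cat("  rewired: ", s$n_rewired, " (",
      paste(names(s$rewiring), unlist(s$rewiring), sep = "=",
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Write every stage output plus the JSON summary under `dir`.
write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  p <- function(f) file.path(dir, f)
  write_stage_tsv(report$interaction_stats, p("interaction_stats.tsv"),
                  "test_enrichment", cfg)
  write_stage_tsv(report$diff_stats, p("hi_vs_lo_stats.tsv"),
                  "compare_conditions", cfg)
  write_stage_tsv(report$calls, p("rewiring_calls.tsv"),
                  "classify_rewiring", cfg)
  write_stage_tsv(report$top_baits, p("top_baits.tsv"),
                  "rank_baits_by_rewiring", cfg)
  write_network_sif(report$diff_net, p("differential_network.sif"))
  write_network_graphml(report$diff_net, p("differential_network.graphml"))
  write_topology_json(report$topology$hi, p("topology_hi.json"))
  write_topology_json(report$topology$lo, p("topology_lo.json"))
  write_stage_tsv(report$flow$hi, p("ifs_hi.tsv"), "ifs_scores", cfg)
  write_stage_tsv(report$flow$lo, p("ifs_lo.tsv"), "ifs_scores", cfg)
  write_stage_tsv(report$flow$diff$shared, p("ifs_differential.tsv"),
                  "differential_ifs", cfg)
  if (!is.null(report$competition)) {
    write_stage_tsv(report$competition, p("competition_fold_changes.tsv"),
                    "dose_fold_change", cfg)
  }
  if (!is.null(report$enrichment)) {
    write_stage_tsv(report$enrichment, p("enrichment.tsv"),
                    "set_enrichment", cfg)
  }
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Recompute headline counts from externally processed study tables
#'
#' For optional full-scale reproduction: reads user-supplied processed
#' interaction tables (TSV, name-matched columns) and recomputes network
#' sizes, the edge union, rewired-interaction counts by category and
#' differential-protein counts with the package's classification rules. If a
#' named list of `reference` counts is supplied, deltas against it are
#' reported. When no tables are provided the report is marked skipped.
#'
#' @param paths Named list of paths: `hi_stats` and `lo_stats` (columns
#'   `bait`, `prey`, `p_value`, `sig_a`), `diff_stats` (those plus
#'   `mean_log2fc`), optional `abundance` (columns `protein`, `p_value`).
#' @param thresholds A [ppi_thresholds()].
#' @param reference Optional named list of expected counts (any of
#'   `hi_edges`, `lo_edges`, `union_edges`, `rewired`, `hi_only`, `lo_only`,
#'   `shared_shifted`, `n_de`).
#' @return A list of class `validation_report` with `computed`, `reference`,
#'   `delta`, and `status`.
#' @export
validate_against_supplementary <- function(paths = list(),
                                           thresholds = ppi_thresholds(),
                                           reference = NULL) {
  need <- c("hi_stats", "lo_stats", "diff_stats")
  have <- intersect(need, names(paths))
  if (length(have) < length(need) ||
      !all(file.exists(unlist(paths[need])))) {
    return(structure(list(
      status = "skipped (external data not provided)",
      computed = NULL, reference = reference, delta = NULL
    ), class = "validation_report"))
  }
  read_checked <- function(path, cols) {
    x <- read_stage_tsv(path)
    missing <- setdiff(cols, names(x))
    if (length(missing) > 0) {
      abort(paste0(path, " lacks column(s): ",
                   paste(missing, collapse = ", "),
                   " (found: ", paste(names(x), collapse = ", "), ")"),
            class = "ppirewire_schema_error")
    }
    x
  }
  gate <- function(x) {
    x |> filter(.data$p_value <= thresholds$p_max,
                .data$sig_a <= thresholds$sig_a_max)
  }
  hi <- gate(read_checked(paths$hi_stats, c("bait", "prey", "p_value",
                                            "sig_a")))
  lo <- gate(read_checked(paths$lo_stats, c("bait", "prey", "p_value",
                                            "sig_a")))
  ds <- read_checked(paths$diff_stats, c("bait", "prey", "p_value", "sig_a",
                                         "mean_log2fc"))
  calls <- classify_rewiring(hi, lo, ds, thresholds)
  cat_counts <- table(factor(calls$category, levels = rewiring_levels()))
  computed <- list(
    hi_edges = nrow(distinct(hi, .data$bait, .data$prey)),
    lo_edges = nrow(distinct(lo, .data$bait, .data$prey)),
    union_edges = nrow(calls),
    rewired = sum(calls$category != "unchanged"),
    hi_only = unname(cat_counts[["hi_only"]]),
    lo_only = unname(cat_counts[["lo_only"]]),
    shared_shifted = unname(cat_counts[["shared_up_hi"]] +
                              cat_counts[["shared_up_lo"]])
  )
  if (!is.null(paths$abundance) && file.exists(paths$abundance)) {
    ab <- read_checked(paths$abundance, c("protein", "p_value"))
    computed$n_de <- sum(ab$p_value <= 0.05)
  }
  delta <- if (!is.null(reference)) {
    common <- intersect(names(reference), names(computed))
    setNames(lapply(common,
                    function(k) computed[[k]] - reference[[k]]), common)
  }
  structure(list(status = "computed", computed = computed,
                 reference = reference, delta = delta),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$status, "\n", sep = "")
  if (!is.null(x$computed)) {
    for (k in names(x$computed)) {
      cat(sprintf("  %-15s %8d%s\n", k, x$computed[[k]],
                  if (!is.null(x$delta[[k]])) {
                    sprintf("  (delta %+d)", x$delta[[k]])
                  } else ""))
    }
  }
  invisible(x)
}
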