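#' Simulation configuration for the synthetic AP-MS SILAC study
#'
#' Bundles every tunable of the synthetic-data generator. The defaults emulate
#' the design of a 95-bait differential EGFR interactome screen: a heavy-tailed
#' prey degree distribution around 33 preys per bait, three biological times
#' two technical replicates with SILAC label swap, empty-vector contaminant
#' background, and planted rewiring fractions matching the proportions of
#' gained, lost and abundance-shifted interactions observed at full scale
#' (roughly 14.3%, 9.2% and 7.4% of the edge union).
#'
#' @param n_baits Number of bait proteins.
#' @param preys_per_bait Mean number of true preys per bait (Poisson).
#' @param frac_hi_only,frac_lo_only,frac_shift Fractions of the edge union
#'   planted as gained-in-hi, gained-in-lo, and abundance-shifted. Their sum
#'   must not exceed 1; the remainder is unchanged.
#' @param noise_sd Standard deviation of per-replicate log2-ratio noise.
#' @param n_bio,n_tech Biological / technical replicates per pulldown.
#' @param contaminant_rate Probability that a given contaminant protein is
#'   detected in a given pulldown (bait or empty-vector).
#' @param n_contaminants Size of the nonspecific-binder pool.
#' @param n_background Non-interacting preys quantified per pulldown at
#'   log2-ratio about 0 (stochastic co-purification background).
#' @param enrich_mean,enrich_sd Normal parameters of the per-edge true
#'   bait-vs-control log2 enrichment.
#' @param min_enrich Floor on planted bait-vs-control enrichment (log2).
#' @param effect_gain Absolute hi-vs-lo log2 effect planted on gained/lost
#'   edges. Presence/absence in AP-MS manifests as detection-limited ratios,
#'   so gains and losses are modelled as large finite shifts (default +/- 4)
#'   rather than infinities.
#' @param effect_shift_range Range of absolute hi-vs-lo log2 effects for
#'   abundance-shifted (shared) edges; minimum must be > 0.
#' @param detect_miss_prob Probability that an edge absent from a condition is
#'   dropped from that condition's pulldown table entirely (otherwise it is
#'   emitted with near-zero enrichment), mimicking stochastic peptide
#'   detection.
#' @param run_offset_sd Standard deviation of the per-MS-run mixing offset
#'   added to every ratio of a run (removed by median centring).
#' @param new_prey_prob Probability that a prey slot introduces a brand-new
#'   prey instead of re-drawing an existing one proportionally to its current
#'   degree (preferential attachment; lower values give stronger hubs).
#' @param hot_baits Indices of baits on which planted rewiring is
#'   concentrated (empty by default: rewiring is spread uniformly).
#' @param hot_bait_boost Odds multiplier applied to the rewired-category
#'   probabilities of hot-bait edges.
#' @param seed Integer seed; all generator draws are reproducible given it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_baits = 10, preys_per_bait = 8, seed = 42)
#' truth <- generate_truth_network(cfg)
sim_config <- function(n_baits = 95,
                       preys_per_bait = 33,
                       frac_hi_only = 634 / 4420,
                       frac_lo_only = 406 / 4420,
                       frac_shift = 328 / 4420,
                       noise_sd = 0.3,
                       n_bio = 3,
                       n_tech = 2,
                       contaminant_rate = 0.05,
                       n_contaminants = 100,
                       n_background = 300,
                       enrich_mean = 3,
                       enrich_sd = 0.5,
                       min_enrich = 1.5,
                       effect_gain = 4,
                       effect_shift_range = c(2, 4),
                       detect_miss_prob = 0.9,
                       run_offset_sd = 0.2,
                       new_prey_prob = 0.4,
                       hot_baits = integer(0),
                       hot_bait_boost = 5,
                       seed = 1L) {
  cfg <- list(
    n_baits = as.integer(n_baits), preys_per_bait = preys_per_bait,
    frac_hi_only = frac_hi_only, frac_lo_only = frac_lo_only,
    frac_shift = frac_shift, noise_sd = noise_sd,
    n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
    contaminant_rate = contaminant_rate, n_contaminants = as.integer(n_contaminants),
    n_background = as.integer(n_background),
    enrich_mean = enrich_mean, enrich_sd = enrich_sd, min_enrich = min_enrich,
    effect_gain = effect_gain, effect_shift_range = effect_shift_range,
    detect_miss_prob = detect_miss_prob, run_offset_sd = run_offset_sd,
    new_prey_prob = new_prey_prob, hot_baits = as.integer(hot_baits),
    hot_bait_boost = hot_bait_boost, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- cfg$frac_hi_only + cfg$frac_lo_only + cfg$frac_shift
  if (any(c(cfg$frac_hi_only, cfg$frac_lo_only, cfg$frac_shift) < 0) || fr > 1) {
    abort("rewiring fractions must be non-negative and sum to at most 1",
          class = "ppirewire_config_error")
  }
  if (cfg$n_baits < 1 || cfg$n_bio < 1 || cfg$n_tech < 1 || cfg$preys_per_bait < 1) {
    abort("all counts must be >= 1", class = "ppirewire_config_error")
  }
  if (cfg$noise_sd < 0) {
    abort("noise_sd must be >= 0 (0 is the deterministic limit)",
          class = "ppirewire_config_error")
  }
  if (cfg$effect_shift_range[1] <= 0 || diff(cfg$effect_shift_range) < 0) {
    abort("effect_shift_range must be positive and non-decreasing",
          class = "ppirewire_config_error")
  }
  invisible(cfg)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a ground-truth differential interaction network
#'
#' Draws a bait-prey union network over one shared prey namespace, with prey
#' slots filled by preferential attachment so that a minority of preys become
#' shared hubs and the bait-side degree distribution is heavy-tailed. Each
#' edge is assigned a rewiring category and a planted hi-vs-lo log2 effect:
#' 0 for unchanged edges, +/- `effect_gain` for gained/lost edges, and a draw
#' from `effect_shift_range` (signed) for abundance-shifted edges.
#'
#' @param config A [sim_config()].
#' @return A `truth_network`: list with `edges` (tibble: bait, prey, category,
#'   effect_size, in_hi, in_lo), `baits`, `contaminants`, and the generating
#'   `config`.
#' @export
generate_truth_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)

  local_seed(config$seed, {
    baits <- sprintf("BAIT%03d", seq_len(config$n_baits))
    prey_degree <- integer(0)   # named; doubles as the prey registry

    edges_by_bait <- vector("list", config$n_baits)
    for (b in seq_len(config$n_baits)) {
      m <- max(1L, rpois(1L, config$preys_per_bait))
      chosen <- character(0)
      while (length(chosen) < m) {
        new_prey <- length(prey_degree) == 0L ||
          runif(1) < config$new_prey_prob
        if (new_prey) {
          prey <- sprintf("PREY%05d", length(prey_degree) + 1L)
          prey_degree[prey] <- 0L
        } else {
          prey <- sample(names(prey_degree), 1L, prob = prey_degree + 1L)
        }
        if (!(prey %in% chosen)) {
          chosen <- c(chosen, prey)
          prey_degree[prey] <- prey_degree[prey] + 1L
        }
      }
      edges_by_bait[[b]] <- tibble(bait = baits[b], prey = chosen)
    }
    edges <- bind_rows(edges_by_bait)

    n_edge <- nrow(edges)
    probs <- c(config$frac_hi_only, config$frac_lo_only,
               config$frac_shift / 2, config$frac_shift / 2)
    probs <- c(probs, 1 - sum(probs))
    hot <- edges$bait %in% baits[config$hot_baits]
    draw_cat <- function(p, n) {
      sample(rewiring_levels(), n, replace = TRUE, prob = p)
    }
    edges$category <- draw_cat(probs, n_edge)
    if (any(hot)) {
      boosted <- probs * c(rep(config$hot_bait_boost, 4), 1)
      edges$category[hot] <- draw_cat(boosted / sum(boosted), sum(hot))
    }

    shift_draw <- function(n) {
      runif(n, config$effect_shift_range[1], config$effect_shift_range[2])
    }
    edges$effect_size <- dplyr::case_when(
      edges$category == "hi_only"      ~ config$effect_gain,
      edges$category == "lo_only"      ~ -config$effect_gain,
      edges$category == "shared_up_hi" ~ shift_draw(n_edge),
      edges$category == "shared_up_lo" ~ -shift_draw(n_edge),
      TRUE                             ~ 0
    )
    edges$in_hi <- edges$category != "lo_only"
    edges$in_lo <- edges$category != "hi_only"

    contaminants <- if (config$n_contaminants > 0) {
      sprintf("CONT%03d", seq_len(config$n_contaminants))
    } else character(0)

    structure(
      list(edges = as_tibble(edges), baits = baits,
           contaminants = contaminants, config = config),
      class = "truth_network"
    )
  })
}

#' @export
print.truth_network <- function(x, ...) {
  cts <- table(factor(x$edges$category, levels = rewiring_levels()))
  cat("<truth_network> ", length(x$baits), " baits, ", nrow(x$edges),
      " union edges (seed ", x$config$seed, ")\n", sep = "")
  cat("  ", paste(names(cts), cts, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Replicate design grid with label-swap orientation: odd biological replicates
# are measured forward, even ones reverse (orientation is a property of the
# labelling of the biological culture, shared by its technical replicates).
replicate_grid <- function(config) {
  grid <- tidyr::expand_grid(bio_rep = seq_len(config$n_bio),
                             tech_rep = seq_len(config$n_tech))
  grid$label_orientation <- if_else(grid$bio_rep %% 2L == 1L,
                                    "forward", "reverse")
  grid$replicate_id <- sprintf("b%dt%d", grid$bio_rep, grid$tech_rep)
  grid
}

# Emit one pulldown run set: every prey in `means` (named numeric) measured in
# every replicate of `grid`, with per-run mixing offsets and label-swap signs.
emit_runs <- function(bait, condition, means, grid, config) {
  if (length(means) == 0) return(NULL)
  n_runs <- nrow(grid)
  offsets <- rnorm(n_runs, 0, config$run_offset_sd)
  rows <- tidyr::expand_grid(prey = names(means), run = seq_len(n_runs))
  mu <- means[rows$prey]
  noise <- rnorm(nrow(rows), 0, config$noise_sd)
  orient <- if_else(grid$label_orientation[rows$run] == "forward", 1, -1)
  tibble(
    bait = bait, prey = rows$prey, condition = condition,
    replicate_id = grid$replicate_id[rows$run],
    bio_rep = grid$bio_rep[rows$run], tech_rep = grid$tech_rep[rows$run],
    label_orientation = grid$label_orientation[rows$run],
    log2_ratio = orient * (mu + noise) + offsets[rows$run]
  )
}

#' Simulate SILAC quantification tables from a truth network
#'
#' Produces the three replicate-level ratio tables the scoring pipeline
#' consumes: bait pulldown vs. common reference per condition, empty-vector
#' control pulldowns per condition, and the direct hi-vs-lo comparison per
#' bait. True interactors receive a positive bait-vs-control log2 enrichment
#' (per-edge draw, floored at `min_enrich`); shifted edges split their planted
#' effect symmetrically across the two conditions; edges absent from a
#' condition are dropped with probability `detect_miss_prob` and otherwise
#' emitted at near-zero enrichment. Background preys and contaminants are
#' quantified at mean 0 so that ratio distributions are mostly null, as in
#' real pulldowns. Label-swapped replicates carry raw ratios of opposite sign
#' (orientation flags recorded); per-run mixing offsets are planted so that
#' naive averaging without normalisation is biased.
#'
#' @param truth A `truth_network`.
#' @param config The [sim_config()] used to generate it (defaults to the one
#'   stored in `truth`).
#' @return A list of class `silac_sim` with tibbles `pulldown`, `control`,
#'   `hi_vs_lo` (QuantTable columns: bait, prey, condition, replicate_id,
#'   bio_rep, tech_rep, label_orientation, log2_ratio) and the `config`.
#' @export
simulate_silac_experiment <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_network"), inherits(config, "sim_config"))
  grid <- replicate_grid(config)
  all_preys <- unique(truth$edges$prey)

  local_seed(config$seed + 1L, {
    edges <- truth$edges
    base_enrich <- pmax(config$min_enrich,
                        rnorm(nrow(edges), config$enrich_mean, config$enrich_sd))
    # Planted effect split across conditions so hi - lo = effect_size for
    # shared edges, with the weaker side floored at 0.5 log2 units: a shifted
    # interaction is still a detectable interaction on both sides.
    e <- edges$effect_size
    down_side <- pmax(0.5, base_enrich - abs(e) / 2)
    edges$enrich_hi <- if_else(e >= 0, down_side + e, down_side)
    edges$enrich_lo <- if_else(e >= 0, down_side, down_side - e)
    edges$enrich_hi[edges$category == "hi_only"] <- base_enrich[edges$category == "hi_only"]
    edges$enrich_lo[edges$category == "lo_only"] <- base_enrich[edges$category == "lo_only"]

    pulldown <- list()
    control <- list()
    hi_vs_lo <- list()

    for (b in truth$baits) {
      eb <- edges[edges$bait == b, ]
      pool <- setdiff(all_preys, eb$prey)
      bg <- if (length(pool) > 0) {
        sample(pool, min(config$n_background, length(pool)))
      } else character(0)

      conts_seen <- character(0)
      for (cond in c("hi", "lo")) {
        present <- if (cond == "hi") eb$in_hi else eb$in_lo
        mu_edge <- if (cond == "hi") eb$enrich_hi else eb$enrich_lo
        means <- setNames(mu_edge, eb$prey)
        # stochastic detection of absent edges at near-zero enrichment
        absent <- which(!present)
        drop <- absent[runif(length(absent)) < config$detect_miss_prob]
        means[absent] <- rnorm(length(absent), 0, 0.1)
        if (length(drop) > 0) means <- means[-drop]

        conts <- truth$contaminants[
          runif(length(truth$contaminants)) < config$contaminant_rate]
        conts_seen <- union(conts_seen, conts)
        means <- c(means, setNames(rep(0, length(bg)), bg),
                   setNames(rep(0, length(conts)), conts))
        pulldown[[paste(b, cond)]] <- emit_runs(b, cond, means, grid, config)
      }

      # direct hi-vs-lo comparison: union edges at their planted effect;
      # background and every contaminant seen in either pulldown at 0, so
      # any prey that can enter a condition network has a direct statistic
      means <- c(setNames(eb$effect_size, eb$prey),
                 setNames(rep(0, length(bg)), bg),
                 setNames(rep(0, length(conts_seen)), conts_seen))
      hi_vs_lo[[b]] <- emit_runs(b, "hi_vs_lo", means, grid, config)
    }

    # empty-vector controls: contaminants only, no planted interactors
    for (cond in c("hi", "lo")) {
      conts <- truth$contaminants[
        runif(length(truth$contaminants)) < config$contaminant_rate]
      means <- setNames(rep(0, length(conts)), conts)
      control[[cond]] <- emit_runs("EMPTY_VECTOR", cond, means, grid, config)
    }

    structure(
      list(pulldown = bind_rows(pulldown), control = bind_rows(control),
           hi_vs_lo = bind_rows(hi_vs_lo), config = config),
      class = "silac_sim"
    )
  })
}

#' @export
print.silac_sim <- function(x, ...) {
  cat("<silac_sim> pulldown rows: ", nrow(x$pulldown),
      ", control rows: ", nrow(x$control),
      ", hi-vs-lo rows: ", nrow(x$hi_vs_lo), "\n", sep = "")
  invisible(x)
}

#' Simulate differential protein abundance and phosphorylation tables
#'
#' Builds a quantified-protein universe (network proteins plus filler up to
#' `n_universe`) and plants `n_de` differentially abundant and `n_dp`
#' differentially phosphorylated proteins. A fraction `overlap_with_rewired`
#' of each planted set is drawn from preys of rewired edges, the remainder
#' from the rest of the universe, so enrichment of rewired nodes in the
#' differential sets is controlled.
#'
#' @param truth A `truth_network`.
#' @param n_de,n_dp Numbers of differential proteins to plant.
#' @param overlap_with_rewired Fraction in `[0, 1]` of each differential set
#'   drawn from rewired-edge preys.
#' @param n_universe Total proteins assayed.
#' @param seed Integer seed.
#' @return List with tibbles `abundance` and `phospho` (columns: protein,
#'   log2_fc, p_value, significant).
#' @export
simulate_protein_tables <- function(truth, n_de = 404, n_dp = 384,
                                    overlap_with_rewired = 0.18,
                                    n_universe = 4685,
                                    seed = truth$config$seed + 2L) {
  stopifnot(inherits(truth, "truth_network"))
  if (overlap_with_rewired < 0 || overlap_with_rewired > 1) {
    abort("overlap_with_rewired must be in [0, 1]",
          class = "ppirewire_config_error")
  }
  network_proteins <- unique(c(truth$edges$bait, truth$edges$prey))
  rewired_preys <- unique(truth$edges$prey[truth$edges$category != "unchanged"])
  n_fill <- max(0L, n_universe - length(network_proteins))
  universe <- c(network_proteins, sprintf("BKGD%05d", seq_len(n_fill)))
  if (n_de > length(universe) || n_dp > length(universe)) {
    abort("more differential proteins requested than proteins in the universe",
          class = "ppirewire_config_error")
  }

  local_seed(seed, {
    plant <- function(n_diff) {
      k_re <- round(n_diff * overlap_with_rewired)
      if (k_re > length(rewired_preys)) {
        abort("overlap_with_rewired requires more rewired preys than exist",
              class = "ppirewire_config_error")
      }
      from_rewired <- sample(rewired_preys, k_re)
      rest_pool <- setdiff(universe, rewired_preys)
      diff_set <- c(from_rewired, sample(rest_pool, n_diff - k_re))
      is_diff <- universe %in% diff_set
      tibble(
        protein = universe,
        log2_fc = if_else(is_diff,
                          sample(c(-1, 1), length(universe), replace = TRUE) *
                            (0.5 + abs(rnorm(length(universe), 1, 0.5))),
                          rnorm(length(universe), 0, 0.3)),
        p_value = if_else(is_diff,
                          runif(length(universe), 0, 0.05),
                          runif(length(universe), 0.05, 1)),
        significant = is_diff
      )
    }
    list(abundance = plant(n_de), phospho = plant(n_dp))
  })
}
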