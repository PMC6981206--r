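#' Significance thresholds for interaction filtering and rewiring calls
#'
#' @param p_max Maximum location-test P value (raw, uncorrected). The joint
#'   gate with `sig_a_max` is applied without multiple-testing correction:
#'   the conjunction of the two raw thresholds is the pipeline's
#'   false-positive control.
#' @param sig_a_max Maximum significance-A value.
#' @param contaminant_max_frequency Fraction of baits in which a prey may be
#'   retained before it is flagged as a nonspecific binder and removed
#'   (frequent-flyer filter).
#' @param exclude Optional character vector of prey identifiers to drop
#'   unconditionally (user-supplied contaminant list).
#' @return A list of class `ppi_thresholds`.
#' @export
ppi_thresholds <- function(p_max = 0.05, sig_a_max = 0.05,
                           contaminant_max_frequency = 0.5,
                           exclude = character(0)) {
  vals <- c(p_max = p_max, sig_a_max = sig_a_max,
            contaminant_max_frequency = contaminant_max_frequency)
  if (any(vals <= 0 | vals > 1)) {
    abort("thresholds must lie in (0, 1]", class = "ppirewire_config_error")
  }
  structure(list(p_max = p_max, sig_a_max = sig_a_max,
                 contaminant_max_frequency = contaminant_max_frequency,
                 exclude = exclude),
            class = "ppi_thresholds")
}

quant_cols <- c("bait", "prey", "condition", "replicate_id", "bio_rep",
                "tech_rep", "label_orientation", "log2_ratio")

check_quant_table <- function(x, arg = deparse(substitute(x))) {
  missing <- setdiff(quant_cols, names(x))
  if (length(missing) > 0) {
    abort(paste0("`", arg, "` is missing QuantTable column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ppirewire_schema_error")
  }
  invisible(x)
}

#' Normalise raw SILAC ratio tables
#'
#' Flips reverse-labelled replicates to the common (forward) orientation and
#' median-centres the log2 ratios of each MS run — each (bait, condition,
#' replicate) ratio set — to zero, removing per-run mixing offsets. The input
#' is not modified.
#'
#' @param raw A QuantTable tibble (see [simulate_silac_experiment()] for the
#'   column dialect).
#' @return A tibble with the same columns, `log2_ratio` oriented and centred.
#' @export
normalize_ratios <- function(raw) {
  check_quant_table(raw)
  bad <- which(is.na(raw$label_orientation) |
                 !(raw$label_orientation %in% c("forward", "reverse")))
  if (length(bad) > 0) {
    abort(paste0("missing/invalid label_orientation in row(s): ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..."),
          class = "ppirewire_schema_error")
  }
  raw |>
    mutate(log2_ratio = if_else(.data$label_orientation == "reverse",
                                -.data$log2_ratio, .data$log2_ratio)) |>
    group_by(.data$bait, .data$condition, .data$replicate_id) |>
    mutate(log2_ratio = .data$log2_ratio -
             median(.data$log2_ratio, na.rm = TRUE)) |>
    ungroup()
}

# Average technical replicates into their biological replicate. Tests then run
# on biological replicates only, avoiding pseudo-replication.
collapse_tech_reps <- function(x) {
  x |>
    group_by(.data$bait, .data$prey, .data$condition, .data$bio_rep) |>
    summarise(log2_ratio = mean(.data$log2_ratio), .groups = "drop")
}

# One- or two-sample location test robust to zero-variance degeneracy:
# a t statistic cannot be formed when every replicate is identical, so the
# P value is set by the sign of the (possibly zero) difference instead of
# propagating NaN: 1 for no difference, 0/1 for a perfect separation in the
# favourable/unfavourable direction.
safe_t_test <- function(x, y = NULL, alternative = "two.sided") {
  degenerate <- stats::var(x) == 0 && (is.null(y) || stats::var(y) == 0)
  if (degenerate) {
    d <- mean(x) - if (is.null(y)) 0 else mean(y)
    p <- if (d == 0) {
      1
    } else if (alternative == "greater") {
      if (d > 0) 0 else 1
    } else if (alternative == "less") {
      if (d < 0) 0 else 1
    } else {
      0
    }
    return(list(p_value = p, degenerate = TRUE))
  }
  ht <- if (is.null(y)) {
    t.test(x, mu = 0, alternative = alternative)
  } else {
    t.test(x, y, alternative = alternative, var.equal = FALSE)
  }
  list(p_value = unname(ht$p.value), degenerate = FALSE)
}

#' Test prey enrichment in bait pulldowns over empty-vector controls
#'
#' One-sided Welch t-test per prey of the bait-pulldown log2 ratios against
#' the control log2 ratios (after collapsing technical into biological
#' replicates). If a prey has fewer than two control replicates of its own,
#' its pulldown ratios are compared against the pooled control ratio
#' distribution of the same condition — empty-vector runs quantify only
#' background binders, so most true preys have no matched control rows.
#'
#' @param bait_rows Normalised QuantTable of bait pulldown rows.
#' @param control_rows Normalised QuantTable of empty-vector rows for the
#'   same condition(s).
#' @return A tibble with one row per (bait, condition, prey): `mean_log2fc`
#'   (mean pulldown minus mean control), `p_value`, `n_replicates`. Preys
#'   with fewer than two pulldown replicates are skipped with a warning.
#' @export
test_enrichment <- function(bait_rows, control_rows) {
  check_quant_table(bait_rows)
  check_quant_table(control_rows)
  bait_bio <- collapse_tech_reps(bait_rows)
  ctrl_bio <- collapse_tech_reps(control_rows)
  no_ctrl <- setdiff(unique(bait_bio$condition), unique(ctrl_bio$condition))
  if (length(no_ctrl) > 0) {
    abort(paste0("no control rows for condition(s): ",
                 paste(no_ctrl, collapse = ", ")),
          class = "ppirewire_input_error")
  }

  skipped <- character(0)
  out <- bait_bio |>
    group_by(.data$bait, .data$condition, .data$prey) |>
    summarise(values = list(.data$log2_ratio), .groups = "drop")

  ctrl_by_prey <- ctrl_bio |>
    group_by(.data$condition, .data$prey) |>
    summarise(ctrl_values = list(.data$log2_ratio), .groups = "drop")
  ctrl_pool <- ctrl_bio |>
    group_by(.data$condition) |>
    summarise(pool = list(.data$log2_ratio), .groups = "drop")

  out <- out |>
    left_join(ctrl_by_prey, by = c("condition", "prey")) |>
    left_join(ctrl_pool, by = "condition")

  res <- purrr::pmap(
    list(out$values, out$ctrl_values, out$pool, out$prey),
    function(x, ctrl, pool, prey) {
      if (length(x) < 2) {
        return(list(p = NA_real_, fc = NA_real_, n = length(x), skip = prey))
      }
      y <- if (!is.null(ctrl) && length(ctrl) >= 2) ctrl else pool
      if (is.null(y) || length(y) < 2) {
        return(list(p = NA_real_, fc = NA_real_, n = length(x), skip = prey))
      }
      tt <- safe_t_test(x, y, alternative = "greater")
      list(p = tt$p_value, fc = mean(x) - mean(y), n = length(x), skip = NA)
    }
  )
  out$p_value <- purrr::map_dbl(res, "p")
  out$mean_log2fc <- purrr::map_dbl(res, "fc")
  out$n_replicates <- purrr::map_int(res, "n")
  skipped <- purrr::map_chr(res, function(r) r$skip %||% NA_character_)
  skipped <- unique(skipped[!is.na(skipped)])
  if (length(skipped) > 0) {
    warn(paste0(length(skipped), " prey(s) skipped for having < 2 usable ",
                "replicates: ", paste(head(skipped, 5), collapse = ", "),
                if (length(skipped) > 5) " ..."))
  }
  out |>
    filter(!is.na(.data$p_value)) |>
    select("bait", "condition", "prey", "mean_log2fc", "p_value",
           "n_replicates")
}

#' Significance-A outlier statistic for log2 fold-changes
#'
#' Percentile-based robust z construction: for a value `r` at or above the
#' median, `z = (r - q50) / (q84.13 - q50)`; below the median,
#' `z = (q50 - r) / (q50 - q15.87)`, where the percentiles are taken from the
#' input vector itself (84.13 and 15.87 are the one-sigma quantiles of a
#' normal distribution, so `z` reduces to an ordinary z-score for Gaussian
#' input). The returned value is the upper-tail normal probability
#' `sig_a = 0.5 * erfc(z / sqrt(2)) = 1 - pnorm(z)`, at most 0.5 (attained at
#' the median) and decreasing in the outlyingness of `r` on either side.
#'
#' When a percentile spread collapses to zero (a point mass at the median, as
#' in noise-free data), the limiting z is used: 0 at the median, infinite off
#' it on a fully degenerate side, or the informative side's spread when only
#' one side is degenerate. A vector of identical values is an error.
#'
#' @param log2fcs Numeric vector of per-prey mean log2 fold-changes; at least
#'   10 finite values are required for the percentiles to be estimable.
#' @return Numeric vector of significance-A values, aligned with the input.
#' @export
significance_a <- function(log2fcs) {
  vals <- log2fcs[is.finite(log2fcs)]
  if (length(vals) < 10) {
    abort("significance_a needs >= 10 finite values to estimate percentiles",
          class = "ppirewire_stat_error")
  }
  q <- quantile(vals, c(0.1587, 0.5, 0.8413), names = FALSE, type = 7)
  lo_spread <- q[2] - q[1]
  hi_spread <- q[3] - q[2]
  if (hi_spread <= 0 && lo_spread <= 0) {
    if (all(vals == vals[1])) {
      abort(paste("all log2 fold-changes identical; ratio distribution is",
                  "pathological - check normalisation and replicate",
                  "structure"),
            class = "ppirewire_stat_error")
    }
    # Point mass at the median with outliers on both sides: the limiting
    # robust z is 0 at the median and infinite off it.
    z <- if_else(log2fcs == q[2], 0, Inf)
    return(pnorm(z, lower.tail = FALSE))
  }
  # one-sided point mass: borrow the informative side's spread
  if (hi_spread <= 0) hi_spread <- lo_spread
  if (lo_spread <= 0) lo_spread <- hi_spread
  z <- if_else(log2fcs >= q[2],
               (log2fcs - q[2]) / hi_spread,
               (q[2] - log2fcs) / lo_spread)
  pnorm(z, lower.tail = FALSE)
}

#' Two-step filter for high-confidence interactors
#'
#' Step 1 retains preys significantly enriched over empty-vector controls
#' (`p_value <= p_max` and `sig_a <= sig_a_max`, jointly). Step 2 removes
#' preys that survive step 1 for more than `contaminant_max_frequency *
#' bait_count` distinct baits — proteins binding a majority of unrelated
#' baits are treated as nonspecific — plus anything on the user exclusion
#' list. Both attrition counts are reported.
#'
#' @param stats Tibble of interaction statistics with columns `bait`, `prey`,
#'   `p_value`, `sig_a` (see [test_enrichment()] and [add_significance_a()]).
#' @param thresholds A [ppi_thresholds()].
#' @param bait_count Total number of baits screened (the denominator of the
#'   frequent-flyer fraction).
#' @param quiet Suppress the attrition messages.
#' @return The retained rows of `stats`.
#' @export
filter_true_interactors <- function(stats, thresholds = ppi_thresholds(),
                                    bait_count, quiet = FALSE) {
  stopifnot(inherits(thresholds, "ppi_thresholds"))
  step1 <- stats |>
    filter(.data$p_value <= thresholds$p_max,
           .data$sig_a <= thresholds$sig_a_max)
  max_baits <- thresholds$contaminant_max_frequency * bait_count
  frequent <- step1 |>
    distinct(.data$prey, .data$bait) |>
    count(.data$prey, name = "n_baits") |>
    filter(.data$n_baits > max_baits) |>
    pull("prey")
  drop <- union(frequent, thresholds$exclude)
  step2 <- step1 |> filter(!(.data$prey %in% drop))
  if (!quiet) {
    inform(sprintf(
      "interactor filter: %d -> %d after significance gates -> %d after removing %d frequent/excluded prey(s)",
      nrow(stats), nrow(step1), nrow(step2), length(drop)))
  }
  step2
}

#' Attach significance-A values to interaction statistics
#'
#' Computes [significance_a()] over the per-prey mean log2 fold-changes,
#' either within each bait experiment (default, matching per-run outlier
#' calling) or pooled across all baits. Bait experiments with fewer than 10
#' preys fall back to the pooled distribution with a warning.
#'
#' @param stats Tibble with columns `bait`, `prey`, `mean_log2fc`.
#' @param per_bait Compute percentiles within each bait experiment.
#' @return `stats` with a `sig_a` column appended.
#' @export
add_significance_a <- function(stats, per_bait = TRUE) {
  pooled <- significance_a(stats$mean_log2fc)
  if (!per_bait) {
    stats$sig_a <- pooled
    return(stats)
  }
  small <- character(0)
  stats <- stats |>
    group_by(.data$bait) |>
    mutate(sig_a = if (dplyr::n() >= 10) {
      significance_a(.data$mean_log2fc)
    } else {
      NA_real_
    }) |>
    ungroup()
  if (anyNA(stats$sig_a)) {
    small <- unique(stats$bait[is.na(stats$sig_a)])
    warn(paste0("bait experiment(s) with < 10 preys use pooled significance-A",
                " percentiles: ", paste(head(small, 5), collapse = ", "),
                if (length(small) > 5) " ..."))
    stats$sig_a[is.na(stats$sig_a)] <- pooled[is.na(stats$sig_a)]
  }
  stats
}

#' Compare prey abundance directly between the two conditions
#'
#' Two-sided one-sample t-test per (bait, prey) of the hi-vs-lo log2 ratios
#' against zero (technical replicates collapsed into biological ones), with
#' significance-A computed over the per-prey mean log2 ratios of the same
#' bait experiment.
#'
#' @param hi_vs_lo Normalised QuantTable of direct hi-vs-lo measurements.
#' @param per_bait_sig_a Compute significance-A per bait experiment (default)
#'   or pooled across baits.
#' @return A tibble with one row per (bait, prey): `mean_log2fc` (hi over
#'   lo), `p_value`, `sig_a`, `n_replicates`.
#' @export
compare_conditions <- function(hi_vs_lo, per_bait_sig_a = TRUE) {
  check_quant_table(hi_vs_lo)
  bio <- collapse_tech_reps(hi_vs_lo)
  skipped <- character(0)
  out <- bio |>
    group_by(.data$bait, .data$prey) |>
    summarise(values = list(.data$log2_ratio), .groups = "drop")
  res <- purrr::map(out$values, function(x) {
    if (length(x) < 2) return(list(p = NA_real_, fc = mean(x), n = length(x)))
    tt <- safe_t_test(x, alternative = "two.sided")
    list(p = tt$p_value, fc = mean(x), n = length(x))
  })
  out$p_value <- purrr::map_dbl(res, "p")
  out$mean_log2fc <- purrr::map_dbl(res, "fc")
  out$n_replicates <- purrr::map_int(res, "n")
  dropped <- out |> filter(is.na(.data$p_value))
  if (nrow(dropped) > 0) {
    warn(paste0(nrow(dropped), " (bait, prey) pair(s) skipped for having ",
                "< 2 replicates"))
  }
  out |>
    filter(!is.na(.data$p_value)) |>
    select("bait", "prey", "mean_log2fc", "p_value", "n_replicates") |>
    add_significance_a(per_bait = per_bait_sig_a)
}

#' Classify interaction rewiring between two condition networks
#'
#' An edge of the union is *rewired* only if its direct hi-vs-lo comparison
#' is significant on both gates (`p_value <= p_max` and `sig_a <= sig_a_max`).
#' Rewired edges present only in the hi network are `hi_only` (gained), only
#' in lo `lo_only` (lost); rewired edges present in both are `shared_up_hi`
#' or `shared_up_lo` by the sign of the hi-vs-lo log2 fold-change. Edges
#' failing the significance gates are `unchanged` — including edges detected
#' in a single network, which are not counted as rewired without statistical
#' support from the direct comparison.
#'
#' @param net_hi_edges,net_lo_edges Tibbles with columns `bait`, `prey`: the
#'   filtered edge sets of the two condition networks.
#' @param diff_stats Output of [compare_conditions()] covering the edge
#'   union.
#' @param thresholds A [ppi_thresholds()].
#' @return A tibble with one row per union edge: `bait`, `prey`, `category`,
#'   `diff_p`, `diff_sig_a`, `log2fc_hi_vs_lo`, `in_hi`, `in_lo`.
#' @export
classify_rewiring <- function(net_hi_edges, net_lo_edges, diff_stats,
                              thresholds = ppi_thresholds()) {
  stopifnot(inherits(thresholds, "ppi_thresholds"))
  hi <- net_hi_edges |> distinct(.data$bait, .data$prey) |> mutate(in_hi = TRUE)
  lo <- net_lo_edges |> distinct(.data$bait, .data$prey) |> mutate(in_lo = TRUE)
  union <- dplyr::full_join(hi, lo, by = c("bait", "prey")) |>
    mutate(in_hi = !is.na(.data$in_hi), in_lo = !is.na(.data$in_lo))

  merged <- union |>
    left_join(diff_stats |>
                select("bait", "prey", diff_p = "p_value",
                       diff_sig_a = "sig_a",
                       log2fc_hi_vs_lo = "mean_log2fc"),
              by = c("bait", "prey"))
  uncovered <- merged |> filter(is.na(.data$diff_p))
  if (nrow(uncovered) > 0) {
    abort(paste0("no hi-vs-lo statistic for edge(s): ",
                 paste(head(paste(uncovered$bait, uncovered$prey, sep = "-"),
                            10), collapse = ", "),
                 if (nrow(uncovered) > 10) " ..."),
          class = "ppirewire_coverage_error")
  }
  merged |>
    mutate(
      significant = .data$diff_p <= thresholds$p_max &
        .data$diff_sig_a <= thresholds$sig_a_max,
      category = dplyr::case_when(
        !.data$significant                ~ "unchanged",
        .data$in_hi & !.data$in_lo        ~ "hi_only",
        .data$in_lo & !.data$in_hi        ~ "lo_only",
        .data$log2fc_hi_vs_lo > 0         ~ "shared_up_hi",
        .data$log2fc_hi_vs_lo < 0         ~ "shared_up_lo",
        TRUE                              ~ "unchanged"
      )
    ) |>
    select("bait", "prey", "category", "diff_p", "diff_sig_a",
           "log2fc_hi_vs_lo", "in_hi", "in_lo")
}
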