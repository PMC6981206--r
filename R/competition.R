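#' Effector catalogue constructor
#'
#' @param name Effector (or pathway-representative) names.
#' @param total_conc Total effector concentrations in nM.
#' @param kd Dissociation constants in nM (lower = higher affinity).
#' @param pathway Optional pathway labels used when comparing against AP-MS
#'   sensitivity scores.
#' @return A tibble of class `effector_spec`.
#' @export
effector_spec <- function(name, total_conc, kd, pathway = NA_character_) {
  if (any(total_conc <= 0) || any(kd <= 0)) {
    abort("total_conc and kd must be positive", class = "ppirewire_config_error")
  }
  out <- tibble(name = as.character(name), total_conc = as.numeric(total_conc),
                kd = as.numeric(kd), pathway = pathway)
  class(out) <- c("effector_spec", class(out))
  out
}

# Conservation function whose unique root in (0, r_total] is the free
# active-GTPase concentration:  g(r) = r * (1 + sum E_i / (K_i + r)) - r_total.
# g is strictly increasing, g(0) = -r_total < 0 and g(r_total) >= 0, so a
# bracketed bisection always converges; Newton steps then polish the root to
# near machine precision.
conservation_fn <- function(r, e_tot, kd, r_total) {
  r * (1 + sum(e_tot / (kd + r))) - r_total
}

#' Solve the equilibrium of effectors competing for one binding site
#'
#' Multiple effectors bind the single effector-binding site of an active
#' GTPase (total concentration `r_total`). At equilibrium the free GTPase
#' concentration `r` satisfies `r_total = r * (1 + sum_i E_i / (K_i + r))`
#' and each complex is `C_i = r * E_i / (K_i + r)`. The root is found by
#' bracketed bisection on `(0, r_total]` followed by Newton polishing.
#'
#' @param effectors An [effector_spec()] (may have zero rows: nothing binds).
#' @param r_total Total active-GTPase concentration (nM).
#' @param tol Relative tolerance on conservation residuals.
#' @param max_iter Iteration cap across bisection plus Newton.
#' @return A list of class `competition_result`: `r_free`, per-effector
#'   tibble `effectors` (complex concentration `complex_conc`, free effector,
#'   `bound_fraction`, `affinity_class`), `r_total`, `residual`,
#'   `iterations`.
#' @export
#' @examples
#' eff <- effector_spec(c("RAF1", "RALGDS"), c(100, 200), c(50, 2000))
#' solve_equilibrium(eff, r_total = 400)
solve_equilibrium <- function(effectors, r_total, tol = 1e-12,
                              max_iter = 200L) {
  if (r_total <= 0) abort("r_total must be positive",
                          class = "ppirewire_config_error")
  if (tol <= 0) abort("tol must be positive", class = "ppirewire_config_error")
  e_tot <- effectors$total_conc
  kd <- effectors$kd
  if (length(e_tot) > 0 && (any(e_tot <= 0) || any(kd <= 0))) {
    abort("negative or zero effector concentrations/Kd",
          class = "ppirewire_config_error")
  }

  if (length(e_tot) == 0) {
    r <- r_total
    iters <- 0L
  } else {
    lo <- 0
    hi <- r_total
    iters <- 0L
    # bisection to a loose bracket
    while (hi - lo > r_total * 1e-6 && iters < max_iter) {
      mid <- (lo + hi) / 2
      if (conservation_fn(mid, e_tot, kd, r_total) < 0) lo <- mid else hi <- mid
      iters <- iters + 1L
    }
    r <- (lo + hi) / 2
    # Newton polishing; the derivative 1 + sum E*K/(K+r)^2 is >= 1
    repeat {
      g <- conservation_fn(r, e_tot, kd, r_total)
      if (abs(g) <= tol * r_total || iters >= max_iter) break
      dg <- 1 + sum(e_tot * kd / (kd + r)^2)
      r_new <- r - g / dg
      if (r_new <= 0 || r_new > r_total) r_new <- max(min(r_new, r_total),
                                                      r / 2)
      r <- r_new
      iters <- iters + 1L
    }
    if (abs(conservation_fn(r, e_tot, kd, r_total)) > tol * r_total * 10) {
      abort(sprintf("equilibrium solver did not converge (residual %.3g)",
                    conservation_fn(r, e_tot, kd, r_total)),
            class = "ppirewire_solver_error")
    }
  }

  complexes <- if (length(e_tot) > 0) r * e_tot / (kd + r) else numeric(0)
  eff_out <- effectors
  if (nrow(eff_out) > 0) {
    eff_out$complex_conc <- complexes
    eff_out$free_conc <- e_tot - complexes
    eff_out$bound_fraction <- complexes / e_tot
    eff_out$affinity_class <- if_else(kd < r_total, "high", "low")
  }
  structure(list(
    r_free = r,
    effectors = as_tibble(eff_out),
    r_total = r_total,
    residual = abs(r + sum(complexes) - r_total) / r_total,
    iterations = iters
  ), class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf("<competition_result> r_total = %.4g nM, r_free = %.4g nM (residual %.2g, %d iterations)\n",
              x$r_total, x$r_free, x$residual, x$iterations))
  if (nrow(x$effectors) > 0) print(x$effectors)
  invisible(x)
}

#' Classify effectors as high- or low-affinity binders
#'
#' An effector is a high-affinity binder when its dissociation constant is
#' smaller than the abundance of the active GTPase, and low-affinity when it
#' is greater. A Kd exactly equal to `r_total` is labelled low (boundary
#' convention: at the boundary the site is half-occupied at most, behaving
#' like the sub-saturated low-affinity regime).
#'
#' @inheritParams solve_equilibrium
#' @return The effector tibble with an `affinity_class` column.
#' @export
classify_affinity <- function(effectors, r_total) {
  effectors |>
    mutate(affinity_class = if_else(.data$kd < r_total, "high", "low"))
}

#' Fold-change of bound fractions between two GTPase doses
#'
#' Solves the competition equilibrium at a low and a high active-GTPase dose
#' and reports, per effector, the ratio of bound fractions
#' `FC_i = bound_fraction(hi) / bound_fraction(lo)` with a dense descending
#' rank. When the high dose exceeds the low dose every fold-change is at
#' least 1, and fold-changes are larger for low-affinity (high-Kd) effectors
#' — raising the dose shifts complex formation towards low-affinity binders.
#'
#' @inheritParams solve_equilibrium
#' @param r_lo,r_hi Active-GTPase concentrations (nM) at the two doses.
#' @param tol Solver tolerance.
#' @return Tibble: `name`, `pathway`, `kd`, `affinity_class`,
#'   `bound_fraction_lo`, `bound_fraction_hi`, `fold_change`, `rank`,
#'   `unbound_at_lo` flag (fold-change reported as `Inf`).
#' @export
dose_fold_change <- function(effectors, r_lo = 150, r_hi = 400, tol = 1e-12) {
  sol_lo <- solve_equilibrium(effectors, r_lo, tol = tol)
  sol_hi <- solve_equilibrium(effectors, r_hi, tol = tol)
  out <- tibble(
    name = effectors$name,
    pathway = effectors$pathway %||% NA_character_,
    kd = effectors$kd,
    affinity_class = if_else(effectors$kd < r_lo, "high", "low"),
    bound_fraction_lo = sol_lo$effectors$bound_fraction,
    bound_fraction_hi = sol_hi$effectors$bound_fraction
  )
  out |>
    mutate(
      unbound_at_lo = .data$bound_fraction_lo == 0,
      fold_change = if_else(.data$unbound_at_lo, Inf,
                            .data$bound_fraction_hi / .data$bound_fraction_lo),
      rank = dplyr::dense_rank(desc(.data$fold_change))
    )
}

#' Bound-complex concentrations over a grid of GTPase doses
#'
#' Dose-response export used to examine how high- and low-affinity
#' effector complexes grow with active-GTPase abundance.
#'
#' @inheritParams solve_equilibrium
#' @param r_grid Numeric vector of active-GTPase concentrations (nM).
#' @return Tibble: `r_total`, `name`, `kd`, `complex_conc`,
#'   `bound_fraction`.
#' @export
dose_response <- function(effectors, r_grid, tol = 1e-12) {
  purrr::map_dfr(r_grid, function(r) {
    sol <- solve_equilibrium(effectors, r, tol = tol)
    sol$effectors |>
      select("name", "kd", "complex_conc", "bound_fraction") |>
      mutate(r_total = r, .before = 1)
  })
}

#' AP-MS sensitivity scores of effector pathways
#'
#' For each pathway, the mean hi-vs-lo log fold-change over the measured
#' preys of that pathway's bait complexes: the sum of fold-changes normalised
#' by the number of preys measured. Log base 2 by default (consistent with
#' SILAC ratios); natural log available.
#'
#' @param diff_stats Output of [compare_conditions()] (columns `bait`,
#'   `prey`, `mean_log2fc`).
#' @param pathway_map Tibble with columns `bait`, `pathway` assigning
#'   effector baits to pathways.
#' @param log Base of the reported fold-changes: `"log2"` or `"ln"`.
#' @return Tibble: `pathway`, `score`, `n_measured`, with a dense descending
#'   `rank`. Pathways with no measured preys are omitted with a warning.
#' @export
sensitivity_from_apms <- function(diff_stats, pathway_map,
                                  log = c("log2", "ln")) {
  log <- match.arg(log)
  scale <- if (log == "ln") base::log(2) else 1
  joined <- diff_stats |>
    inner_join(pathway_map, by = "bait")
  empty <- setdiff(unique(pathway_map$pathway), unique(joined$pathway))
  if (length(empty) > 0) {
    warn(paste0("pathway(s) with no measured preys omitted: ",
                paste(empty, collapse = ", ")))
  }
  joined |>
    group_by(.data$pathway) |>
    summarise(score = sum(.data$mean_log2fc * scale) / dplyr::n(),
              n_measured = dplyr::n(), .groups = "drop") |>
    arrange(desc(.data$score)) |>
    mutate(rank = dplyr::dense_rank(desc(.data$score)))
}

#' Rank agreement between model fold-changes and AP-MS sensitivity
#'
#' Spearman rank correlation between model-predicted bound-fraction
#' fold-changes and experimentally derived pathway sensitivity scores over
#' the pathways common to both.
#'
#' @param model_fcs Output of [dose_fold_change()] with a `pathway` column.
#' @param sensitivity_scores Output of [sensitivity_from_apms()].
#' @return List: `rho`, `p_value`, `n` (shared pathways), and the joined
#'   tibble `pairs`.
#' @export
rank_agreement <- function(model_fcs, sensitivity_scores) {
  pairs <- model_fcs |>
    filter(!is.na(.data$pathway)) |>
    group_by(.data$pathway) |>
    summarise(model_fc = mean(.data$fold_change), .groups = "drop") |>
    inner_join(sensitivity_scores |> select("pathway", "score"),
               by = "pathway")
  if (nrow(pairs) < 3) {
    abort("need at least 3 shared pathways for a rank correlation",
          class = "ppirewire_input_error")
  }
  ct <- suppressWarnings(
    cor.test(pairs$model_fc, pairs$score, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(pairs),
       pairs = pairs)
}
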