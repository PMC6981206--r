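rewiring_palette <- function() {
  c(hi_only = "#c0392b", shared_up_hi = "#e67e22",
    lo_only = "#2c5aa0", shared_up_lo = "#5dade2",
    unchanged = "grey70")
}

#' Bar chart of rewiring-category counts
#'
#' @param calls Rewiring calls from [classify_rewiring()] (or
#'   `tidy(report)`).
#' @return A ggplot: gained/lost/shifted/unchanged edge counts.
#' @export
plot_rewiring_counts <- function(calls) {
  counts <- calls |>
    count(category = factor(.data$category, levels = rewiring_levels()),
          .drop = FALSE)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = rewiring_palette()) +
    ggplot2::labs(x = NULL, y = "interactions",
                  title = "Interaction rewiring between conditions") +
    ggplot2::theme_minimal()
}

#' Rewired-interaction counts of the top baits
#'
#' @param top_baits Output of [rank_baits_by_rewiring()].
#' @return A ggplot bar chart, most-rewired bait first.
#' @export
plot_top_baits <- function(top_baits) {
  ggplot2::ggplot(top_baits,
                  ggplot2::aes(x = stats::reorder(.data$bait,
                                                  .data$n_rewired),
                               y = .data$n_rewired)) +
    ggplot2::geom_col(fill = "#c0392b") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "rewired interactions",
                  title = "Most rewired baits") +
    ggplot2::theme_minimal()
}

#' Dose-response curves of effector complex formation
#'
#' Plots bound-complex concentration against active-GTPase abundance for
#' each effector, optionally marking the two cellular doses.
#'
#' @param effectors An [effector_spec()].
#' @param r_grid Grid of active-GTPase concentrations (nM).
#' @param doses Optional doses to mark with vertical dashed lines.
#' @return A ggplot.
#' @export
plot_dose_response <- function(effectors,
                               r_grid = seq(10, 1000, by = 10),
                               doses = c(150, 400)) {
  dr <- dose_response(effectors, r_grid)
  p <- ggplot2::ggplot(dr, ggplot2::aes(x = .data$r_total,
                                        y = .data$complex_conc,
                                        colour = .data$name)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "active GTPase (nM)", y = "complex (nM)",
                  colour = "effector",
                  title = "Effector competition for the single binding site") +
    ggplot2::theme_minimal()
  if (length(doses) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = doses, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' @describeIn plot_dose_response Bound fractions of a solved equilibrium.
#' @param object A `competition_result`.
#' @param ... Unused.
#' @method autoplot competition_result
#' @export
autoplot.competition_result <- function(object, ...) {
  ggplot2::ggplot(object$effectors,
                  ggplot2::aes(x = stats::reorder(.data$name,
                                                  .data$bound_fraction),
                               y = .data$bound_fraction,
                               fill = .data$affinity_class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(high = "#2c5aa0",
                                          low = "#c0392b")) +
    ggplot2::labs(x = NULL, y = "bound fraction", fill = "affinity",
                  title = sprintf("Equilibrium at %.0f nM active GTPase",
                                  object$r_total)) +
    ggplot2::theme_minimal()
}

#' Scatter of per-node information flow in the two networks
#'
#' @param object An `ifs_diff` from [differential_ifs()].
#' @param ... Unused.
#' @return A ggplot of hi vs lo share-of-flow on log scales with flagged
#'   nodes highlighted.
#' @method autoplot ifs_diff
#' @export
autoplot.ifs_diff <- function(object, ...) {
  d <- object$shared |>
    filter(is.finite(.data$ratio_hi_vs_lo)) |>
    mutate(flag = dplyr::case_when(
      .data$tf_flag ~ "sink shifted",
      .data$node_flag ~ "node shifted",
      TRUE ~ "stable"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ifs_norm_lo,
                                  y = .data$ifs_norm_hi,
                                  colour = .data$flag)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`node shifted` = "#c0392b",
                                            `sink shifted` = "#8e44ad",
                                            stable = "grey60")) +
    ggplot2::labs(x = "share of flow (lo)", y = "share of flow (hi)",
                  colour = NULL, title = "Differential information flow") +
    ggplot2::theme_minimal()
}

#' Degree distribution with the fitted power law
#'
#' @param object A `topology_report`.
#' @param ... Unused.
#' @return A ggplot of `P(k)` against `k` on log-log axes with the
#'   least-squares fit line.
#' @method autoplot topology_report
#' @export
autoplot.topology_report <- function(object, ...) {
  deg <- object$nodes$degree
  dd <- table(deg[deg >= 1])
  d <- tibble(k = as.numeric(names(dd)),
              pk = as.numeric(dd) / sum(dd))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$pk)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(k)",
                  title = sprintf("Degree distribution (exponent %.2f, R2 %.2f)",
                                  object$network$powerlaw_exponent,
                                  object$network$powerlaw_r2)) +
    ggplot2::theme_minimal()
  if (is.finite(object$network$powerlaw_exponent)) {
    fit <- stats::lm(log10(pk) ~ log10(k), data = d)
    d$fit <- 10^stats::predict(fit)
    p <- p + ggplot2::geom_line(data = d,
                                ggplot2::aes(y = .data$fit),
                                colour = "#c0392b")
  }
  p
}
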