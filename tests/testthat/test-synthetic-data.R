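small_cfg <- function(...) {
  sim_config(n_baits = 6, preys_per_bait = 10, n_contaminants = 20,
             n_background = 30, seed = 11, ...)
}

test_that("zero rewiring fractions give identical hi and lo edge sets", {
  cfg <- small_cfg(frac_hi_only = 0, frac_lo_only = 0, frac_shift = 0)
  truth <- generate_truth_network(cfg)
  expect_true(all(truth$edges$category == "unchanged"))
  expect_true(all(truth$edges$effect_size == 0))
  expect_true(all(truth$edges$in_hi & truth$edges$in_lo))
})

test_that("generated edge totals match the configured study scale", {
  cfg <- sim_config(n_baits = 95, preys_per_bait = 33,
                    frac_hi_only = 0, frac_lo_only = 0, frac_shift = 0,
                    seed = 5)
  truth <- generate_truth_network(cfg)
  n_hi <- sum(truth$edges$in_hi)
  expect_gt(n_hi, 0.9 * 95 * 33)
  expect_lt(n_hi, 1.1 * 95 * 33)
})

test_that("the truth generator is deterministic given the seed", {
  cfg <- small_cfg()
  t1 <- generate_truth_network(cfg)
  t2 <- generate_truth_network(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_silac_experiment(t1)
  s2 <- simulate_silac_experiment(t2)
  expect_identical(s1, s2)
  p1 <- simulate_protein_tables(t1, n_de = 20, n_dp = 20, n_universe = 200)
  p2 <- simulate_protein_tables(t2, n_de = 20, n_dp = 20, n_universe = 200)
  expect_identical(p1, p2)
})

test_that("category fractions and effect sizes respect the config", {
  cfg <- sim_config(n_baits = 40, preys_per_bait = 25,
                    frac_hi_only = 0.2, frac_lo_only = 0.1,
                    frac_shift = 0.1, effect_shift_range = c(2, 4),
                    seed = 3)
  truth <- generate_truth_network(cfg)
  frac <- table(truth$edges$category) / nrow(truth$edges)
  expect_equal(unname(frac[["hi_only"]]), 0.2, tolerance = 0.15)
  expect_equal(unname(frac[["lo_only"]]), 0.1, tolerance = 0.25)
  rewired <- truth$edges$category != "unchanged"
  expect_true(all(abs(truth$edges$effect_size[rewired]) >= 2))
  expect_true(all(truth$edges$effect_size[!rewired] == 0))
  # presence pattern follows the category semantics
  expect_true(all(!truth$edges$in_lo[truth$edges$category == "hi_only"]))
  expect_true(all(!truth$edges$in_hi[truth$edges$category == "lo_only"]))
  expect_true(all(truth$edges$in_hi[truth$edges$category != "lo_only"]))
})

test_that("contaminants live in their own namespace and fill the controls", {
  cfg <- small_cfg(contaminant_rate = 0.3)
  truth <- generate_truth_network(cfg)
  expect_length(intersect(truth$contaminants, truth$edges$prey), 0)
  sim <- simulate_silac_experiment(truth)
  expect_true(all(sim$control$prey %in% truth$contaminants))
  expect_true(all(sim$control$bait == "EMPTY_VECTOR"))
  # contaminant appearance rate in pulldowns near the configured rate
  appear <- sim$pulldown |>
    dplyr::distinct(bait, condition, prey) |>
    dplyr::filter(prey %in% truth$contaminants) |>
    nrow()
  n_slots <- cfg$n_baits * 2 * cfg$n_contaminants
  expect_equal(appear / n_slots, 0.3, tolerance = 0.3)
})

test_that("replicate ratios follow the planted effects under normal noise", {
  cfg <- sim_config(n_baits = 10, preys_per_bait = 20, noise_sd = 0.5,
                    frac_hi_only = 0, frac_lo_only = 0, frac_shift = 1,
                    effect_shift_range = c(2, 2), run_offset_sd = 1e-9,
                    n_background = 10, n_contaminants = 5, seed = 21)
  truth <- generate_truth_network(cfg)
  sim <- simulate_silac_experiment(truth)
  oriented <- sim$hi_vs_lo |>
    dplyr::mutate(val = ifelse(label_orientation == "reverse",
                               -log2_ratio, log2_ratio)) |>
    dplyr::group_by(bait, prey) |>
    dplyr::summarise(m = mean(val), n = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(truth$edges, by = c("bait", "prey"))
  # sample mean within 3 standard errors of the planted effect for >= 99%
  ok <- abs(oriented$m - oriented$effect_size) <= 3 * 0.5 / sqrt(6)
  expect_gte(mean(ok), 0.99)
})

test_that("label-swapped replicates disagree before orientation correction", {
  cfg <- small_cfg(frac_hi_only = 0, frac_lo_only = 0, frac_shift = 1,
                   effect_shift_range = c(4, 4), noise_sd = 0.05,
                   run_offset_sd = 1e-9)
  truth <- generate_truth_network(cfg)
  sim <- simulate_silac_experiment(truth)
  raw <- sim$hi_vs_lo |>
    dplyr::inner_join(truth$edges |> dplyr::filter(effect_size == 4),
                      by = c("bait", "prey"))
  fwd <- raw$log2_ratio[raw$label_orientation == "forward"]
  rev <- raw$log2_ratio[raw$label_orientation == "reverse"]
  expect_true(all(fwd > 0))
  expect_true(all(rev < 0))
  norm <- normalize_ratios(sim$hi_vs_lo) |>
    dplyr::inner_join(truth$edges |> dplyr::filter(effect_size == 4),
                      by = c("bait", "prey"))
  expect_true(all(norm$log2_ratio > 0))
})

test_that("protein tables respect the planted rewired overlap", {
  cfg <- small_cfg()
  truth <- generate_truth_network(cfg)
  rewired <- unique(truth$edges$prey[truth$edges$category != "unchanged"])

  full <- simulate_protein_tables(truth, n_de = length(rewired),
                                  n_dp = 5, overlap_with_rewired = 1,
                                  n_universe = 300)
  de <- full$abundance$protein[full$abundance$significant]
  expect_true(all(de %in% rewired))

  none <- simulate_protein_tables(truth, n_de = 30, n_dp = 5,
                                  overlap_with_rewired = 0,
                                  n_universe = 300)
  de0 <- none$abundance$protein[none$abundance$significant]
  expect_length(intersect(de0, rewired), 0)

  expect_error(simulate_protein_tables(truth, n_de = 400, n_dp = 5,
                                       n_universe = 300),
               class = "ppirewire_config_error")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_hi_only = 0.6, frac_lo_only = 0.6),
               class = "ppirewire_config_error")
  expect_error(sim_config(noise_sd = -0.1), class = "ppirewire_config_error")
  expect_error(sim_config(n_bio = 0), class = "ppirewire_config_error")
})

test_that("rewiring concentrates on designated hot baits", {
  cfg <- sim_config(n_baits = 12, preys_per_bait = 25,
                    frac_hi_only = 0.05, frac_lo_only = 0.03,
                    frac_shift = 0.02, hot_baits = 1:3,
                    hot_bait_boost = 8, seed = 17)
  truth <- generate_truth_network(cfg)
  per_bait <- truth$edges |>
    dplyr::group_by(bait) |>
    dplyr::summarise(n_rw = sum(category != "unchanged")) |>
    dplyr::arrange(dplyr::desc(n_rw))
  expect_setequal(per_bait$bait[1:3], sprintf("BAIT%03d", 1:3))
})
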