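one_run <- function(values, orientation = "forward") {
  tibble::tibble(
    bait = "B1", prey = sprintf("P%d", seq_along(values)), condition = "hi",
    replicate_id = "b1t1", bio_rep = 1L, tech_rep = 1L,
    label_orientation = orientation, log2_ratio = values)
}

test_that("normalisation flips reverse labels and median-centres each run", {
  # already oriented with run median 0: identity
  x <- one_run(c(-1, 0, 1))
  expect_equal(normalize_ratios(x)$log2_ratio, c(-1, 0, 1))

  # reverse-labelled run: ratios change sign (run median stays 0)
  r <- one_run(c(-1.3, 0, 1.3), orientation = "reverse")
  expect_equal(normalize_ratios(r)$log2_ratio, c(1.3, 0, -1.3))

  # median centring within one run
  expect_equal(normalize_ratios(one_run(c(1, 2, 3)))$log2_ratio, c(-1, 0, 1))

  # centring is per run, not across runs
  two <- dplyr::bind_rows(one_run(c(1, 2, 3)),
                          one_run(c(11, 12, 13)) |>
                            dplyr::mutate(replicate_id = "b2t1", bio_rep = 2L))
  expect_equal(normalize_ratios(two)$log2_ratio, rep(c(-1, 0, 1), 2))

  bad <- one_run(c(1, 2, 3))
  bad$label_orientation[2] <- NA
  expect_error(normalize_ratios(bad), class = "ppirewire_schema_error")

  # input is not modified in place
  before <- one_run(c(1, 2, 3))
  invisible(normalize_ratios(before))
  expect_equal(before$log2_ratio, c(1, 2, 3))
})

test_that("enrichment testing is one-sided against empty-vector controls", {
  bait <- quant_rows("B1", "P1", c(3.1, 2.9, 3.0, 3.2, 2.8, 3.0))
  ctrl <- quant_rows("EMPTY", "P1", c(0.0, 0.1, -0.1, 0.0, 0.05, -0.05))
  st <- test_enrichment(bait, ctrl)
  expect_lt(st$p_value, 0.001)
  expect_equal(st$mean_log2fc, 3.0, tolerance = 1e-6)
  expect_equal(st$n_replicates, 6L)

  # identical distributions: zero difference, one-sided p = 0.5
  same <- test_enrichment(quant_rows("B1", "P1", c(1, 2, 3)),
                          quant_rows("EMPTY", "P1", c(1, 2, 3)))
  expect_equal(same$p_value, 0.5)

  # depletion: one-sided p beyond 0.5
  low <- test_enrichment(quant_rows("B1", "P1", c(-2, -2.2, -1.9)),
                         quant_rows("EMPTY", "P1", c(0, 0.1, -0.1)))
  expect_gt(low$p_value, 0.5)
})

test_that("preys without matched control rows use the pooled control null", {
  bait <- dplyr::bind_rows(quant_rows("B1", "P1", c(3.0, 3.1, 2.9)),
                           quant_rows("B1", "P2", c(0.0, 0.1, -0.1)))
  ctrl <- dplyr::bind_rows(quant_rows("EMPTY", "C1", c(0.05, -0.05, 0)),
                           quant_rows("EMPTY", "C2", c(0.1, -0.1, 0)))
  st <- test_enrichment(bait, ctrl)
  expect_equal(nrow(st), 2L)
  expect_lt(st$p_value[st$prey == "P1"], 0.01)
  expect_gt(st$p_value[st$prey == "P2"], 0.2)
})

test_that("single-replicate preys are skipped with a warning, not dropped silently", {
  bait <- dplyr::bind_rows(quant_rows("B1", "P1", c(3.0, 3.1, 2.9)),
                           quant_rows("B1", "P2", 2.5))
  ctrl <- quant_rows("EMPTY", "C1", c(0.05, -0.05, 0))
  expect_warning(st <- test_enrichment(bait, ctrl), "skipped")
  expect_equal(st$prey, "P1")
})

test_that("significance A matches the percentile robust-z construction", {
  # a dense normal grid pins the percentiles at their theoretical values
  vals <- qnorm(ppoints(2001))
  sig <- significance_a(c(vals, 1.96, 0))
  expect_equal(sig[length(vals) + 1], 0.025, tolerance = 0.01)
  expect_equal(sig[length(vals) + 2], 0.5, tolerance = 0.01)
  expect_true(all(sig > 0 & sig <= 0.5 + 1e-9))

  # location invariance
  shifted <- significance_a(c(vals, 1.96, 0) + 17)
  expect_equal(sig, shifted)

  # symmetric outliers on both sides
  expect_equal(sig[which.min(abs(c(vals, 1.96, 0) - (-1.96)))], 0.025,
               tolerance = 0.005)

  expect_error(significance_a(rnorm(5)), class = "ppirewire_stat_error")
  expect_error(significance_a(rep(1, 20)), class = "ppirewire_stat_error")
})

test_that("the two-step filter applies both gates then the frequency rule", {
  stats <- tibble::tibble(
    bait = rep(sprintf("B%02d", 1:95), each = 2),
    prey = rep(c("FREQ", "RARE"), 95),
    p_value = c(rbind(rep(0.01, 95), rep(0.01, 95))),
    sig_a = 0.01
  )
  # RARE passes for 30 baits only; FREQ for 60 of 95
  stats$p_value[stats$prey == "RARE"][31:95] <- 0.2
  stats$p_value[stats$prey == "FREQ"][61:95] <- 0.2
  kept <- filter_true_interactors(stats,
                                  ppi_thresholds(contaminant_max_frequency = 0.5),
                                  bait_count = 95, quiet = TRUE)
  expect_false("FREQ" %in% kept$prey)   # 60 > 47.5 baits: frequent flyer
  expect_true("RARE" %in% kept$prey)
  expect_true(all(kept$p_value <= 0.05))

  # p = 0.2 rows are gone at step 1
  expect_equal(sum(kept$prey == "RARE"), 30L)

  # exclusion list removes preys regardless of significance
  kept2 <- filter_true_interactors(
    stats, ppi_thresholds(exclude = "RARE"), bait_count = 95, quiet = TRUE)
  expect_false("RARE" %in% kept2$prey)
})

test_that("condition comparison is two-sided and symmetric under negation", {
  mk <- function(vals) {
    purrr::map_dfr(1:12, function(i) {
      quant_rows("B1", sprintf("P%02d", i), if (i == 1) vals else rnorm(6, 0, 0.1),
                 condition = "hi_vs_lo")
    })
  }
  set.seed(42)
  tab <- mk(c(2.1, 1.9, 2.0, 2.2, 1.8, 2.0))
  st <- suppressWarnings(compare_conditions(tab))
  hit <- st[st$prey == "P01", ]
  expect_lt(hit$p_value, 0.01)
  expect_lt(hit$sig_a, 0.05)
  expect_equal(hit$mean_log2fc, 2.0, tolerance = 1e-6)

  neg <- tab |> dplyr::mutate(log2_ratio = -log2_ratio)
  st_neg <- suppressWarnings(compare_conditions(neg))
  expect_equal(st_neg$p_value, st$p_value)
  expect_equal(st_neg$mean_log2fc, -st$mean_log2fc)
  expect_equal(st_neg$sig_a, st$sig_a)

  # all-zero ratios: no evidence, p = 1 under the zero-variance convention
  zero <- quant_rows("B2", "PZ", rep(0, 6), condition = "hi_vs_lo")
  st0 <- suppressWarnings(compare_conditions(
    dplyr::bind_rows(tab, zero), per_bait_sig_a = FALSE))
  expect_equal(st0$p_value[st0$prey == "PZ"], 1)
})

test_that("rewiring classification follows the joint significance gate", {
  hi <- tibble::tibble(bait = "B1", prey = c("GAIN", "NOISY", "SH_HI", "SH_LO", "SAME"))
  lo <- tibble::tibble(bait = "B1", prey = c("LOSS", "SH_HI", "SH_LO", "SAME"))
  ds <- tibble::tibble(
    bait = "B1",
    prey = c("GAIN", "NOISY", "LOSS", "SH_HI", "SH_LO", "SAME"),
    mean_log2fc = c(4, 3, -4, 1.5, -1.5, 0.05),
    p_value = c(0.001, 0.4, 0.002, 0.01, 0.01, 0.8),
    sig_a = c(0.01, 0.2, 0.01, 0.02, 0.02, 0.5),
    n_replicates = 3L
  )
  calls <- classify_rewiring(hi, lo, ds)
  cat_of <- function(p) calls$category[calls$prey == p]
  expect_equal(cat_of("GAIN"), "hi_only")
  expect_equal(cat_of("NOISY"), "unchanged")  # single-network but not significant
  expect_equal(cat_of("LOSS"), "lo_only")
  expect_equal(cat_of("SH_HI"), "shared_up_hi")
  expect_equal(cat_of("SH_LO"), "shared_up_lo")
  expect_equal(cat_of("SAME"), "unchanged")

  # categories partition the union
  expect_equal(nrow(calls), length(union(paste(hi$bait, hi$prey),
                                         paste(lo$bait, lo$prey))))

  # an uncovered edge is an error that names the edge
  expect_error(classify_rewiring(hi, lo, ds[-1, ]),
               class = "ppirewire_coverage_error")

  # swapping hi/lo mirrors the categories exactly
  ds_swap <- ds |> dplyr::mutate(mean_log2fc = -mean_log2fc)
  swapped <- classify_rewiring(lo, hi, ds_swap)
  mirror <- c(hi_only = "lo_only", lo_only = "hi_only",
              shared_up_hi = "shared_up_lo", shared_up_lo = "shared_up_hi",
              unchanged = "unchanged")
  joined <- dplyr::inner_join(calls, swapped, by = c("bait", "prey"))
  expect_equal(unname(mirror[joined$category.x]), joined$category.y)

  # tightening p_max never grows the rewired set
  loose <- sum(calls$category != "unchanged")
  tight <- classify_rewiring(hi, lo, ds, ppi_thresholds(p_max = 0.005))
  expect_lte(sum(tight$category != "unchanged"), loose)
  expect_true(all(tight$prey[tight$category != "unchanged"] %in%
                    calls$prey[calls$category != "unchanged"]))
})

test_that("noise-free simulation is classified exactly as planted", {
  cfg <- sim_config(n_baits = 8, preys_per_bait = 15, noise_sd = 0,
                    run_offset_sd = 0, detect_miss_prob = 1,
                    new_prey_prob = 1, n_background = 150,
                    n_contaminants = 20, contaminant_rate = 0.3, seed = 9)
  truth <- generate_truth_network(cfg)
  sim <- simulate_silac_experiment(truth)
  pd <- normalize_ratios(sim$pulldown)
  ct <- normalize_ratios(sim$control)
  hv <- normalize_ratios(sim$hi_vs_lo)
  stats <- suppressWarnings(test_enrichment(pd, ct)) |> add_significance_a()
  kept <- stats |>
    dplyr::group_by(condition) |>
    dplyr::group_map(~ filter_true_interactors(.x, bait_count = 8,
                                               quiet = TRUE))
  names(kept) <- c("hi", "lo")
  ds <- suppressWarnings(compare_conditions(hv))
  calls <- classify_rewiring(kept$hi, kept$lo, ds)
  merged <- dplyr::inner_join(truth$edges, calls, by = c("bait", "prey"),
                              suffix = c("_true", "_call"))
  expect_equal(nrow(merged), nrow(truth$edges))
  expect_equal(merged$category_call, merged$category_true)
})
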