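pgr <- point_group("222")

merged_ref <- function(sim, pg = pgr) {
  obs <- wedgemerge:::pool_observations(sim$datasets, pg)
  sc <- scale_datasets(obs, sim$truth_table$id[1])
  scaled <- wedgemerge:::apply_scaling(obs, sc)
  list(scaled = scaled, scaling = sc,
       merged = merge_observations(scaled))
}

test_that("Tukey fence flags match a direct quartile computation", {
  v <- c(0.90, 0.91, 0.92, 0.89, 0.30)
  r <- tukey_lower_fence(v)
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(r$threshold, q[1] - 1.5 * (q[2] - q[1]))
  expect_equal(which(r$flags), 5L)
  ## random inputs: oracle equality of the fence
  wedgemerge:::with_seed(13, {
    for (i in 1:10) {
      x <- stats::rnorm(30)
      f <- tukey_lower_fence(x)
      qq <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      expect_equal(f$threshold, qq[1] - 1.5 * (qq[2] - qq[1]))
      expect_equal(f$flags, x < f$threshold)
    }
  })
  ## constant values: IQR 0, nothing flagged
  expect_false(any(tukey_lower_fence(rep(0.9, 10))$flags))
  ## k = Inf flags nothing
  expect_false(any(tukey_lower_fence(v, k = Inf)$flags))
  ## fewer than 4 values: warning, no rejection
  expect_warning(r4 <- tukey_lower_fence(c(1, 2, 3)), "fewer than 4")
  expect_false(any(r4$flags))
})

test_that("per-frame CC is high for clean frames and low for noise frames", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 8, completeness_per_wedge = 0.5,
                         noise_c = 0.03, seed = 61,
                         outlier_spec = list(bad_frame_rate = 0.1))
  mr <- merged_ref(sim)
  fcc <- per_frame_cc(mr$scaled, mr$merged)
  fcc[, bad := paste(dataset, frame) %in%
        paste(sim$bad_frames$dataset, sim$bad_frames$frame)]
  expect_gt(stats::median(fcc[bad == FALSE & !low_evidence, cc]), 0.9)
  expect_gt(stats::quantile(fcc[bad == FALSE & !low_evidence, cc], 0.05), 0.7)
  expect_lt(max(fcc[bad == TRUE & !low_evidence, cc]), 0.5)
  ## frames with < 3 matched observations are flagged, never rejected
  expect_true(all(fcc[n < 3, low_evidence]))
})

test_that("frame rejection removes injected bad frames, keeps the interior", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 10,
                         completeness_per_wedge = 0.5, noise_c = 0.03,
                         seed = 62, outlier_spec = list(bad_frame_rate = 0.1))
  mr <- merged_ref(sim)
  fcc <- per_frame_cc(mr$scaled, mr$merged)
  fr <- reject_bad_frames(sim$datasets, fcc)
  ev <- evaluate_against_truth(sim, rejected_frames = fr$rejected_frames)
  expect_gte(ev$frame_recall, 0.95)
  expect_lt(ev$frame_fp_rate, 0.02)
  ## absolute mode removes exactly the frames below the threshold
  fr2 <- reject_bad_frames(sim$datasets, fcc, mode = 0.5)
  want <- fcc[!(low_evidence) & is.finite(cc) & cc < 0.5,
              paste(dataset, frame)]
  expect_setequal(fr2$rejected_frames[, paste(dataset, frame)], want)
})

test_that("clean cohorts have a low frame false-positive rate", {
  truth <- small_truth()
  fp <- vapply(1:5, function(i) {
    sim <- simulate_wedges(truth, n_datasets = 10,
                           completeness_per_wedge = 0.6, noise_c = 0.03,
                           seed = 600 + i)
    mr <- merged_ref(sim)
    fcc <- per_frame_cc(mr$scaled, mr$merged)
    fr <- reject_bad_frames(sim$datasets, fcc)
    nrow(fr$rejected_frames) /
      sum(vapply(sim$datasets, function(d) d$frame_end, numeric(1)))
  }, numeric(1))
  expect_lt(mean(fp), 0.02)
})

test_that("dataset metrics flag non-isomorphous members beyond the fences", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 12,
                         completeness_per_wedge = 0.5, noise_c = 0.02,
                         sigma_model = "counting", seed = 63,
                         outlier_spec = list(nonisomorphous = 0.1))
  mr <- merged_ref(sim)
  ems <- list()
  for (id in sim$truth_table$id) {
    ems[[id]] <- refine_error_model(mr$scaled, id)
  }
  metrics <- dataset_quality_metrics(mr$scaled, mr$merged, mr$scaling, ems)
  expect_equal(nrow(metrics), 12)
  bad_ids <- sim$truth_table[outlier == "nonisomorphous", id]
  good_R <- metrics[!(dataset %in% bad_ids), R]
  fence <- tukey_fences(metrics$R)$upper
  expect_true(all(metrics[dataset %in% bad_ids, R] >
                    max(good_R)))
  ## rejection by {R} catches them
  rb <- reject_bad_datasets(metrics, criteria = c("R"))
  expect_true(all(bad_ids %in% rb$rejected$dataset))
  ## empty criteria: nothing rejected
  rb0 <- reject_bad_datasets(metrics, criteria = character(0))
  expect_length(rb0$kept_ids, 12)
  ## a clean isomorphous dataset has a small merging residual
  expect_lt(min(metrics$R), 0.1)
})

test_that("rejection cycles: clean data stop early with two merges", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 6, completeness_per_wedge = 0.5,
                         noise_c = 0.03, seed = 64)
  res <- run_rejection_cycles(sim$datasets, pgr, list(seed = 9))
  expect_equal(res$n_merges, 2L)
  expect_equal(nrow(res$log$cycle1$rejected_frames), 0)
  expect_length(res$datasets, 6)
})

test_that("max_cycles = 1 performs only frame rejection", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 8, completeness_per_wedge = 0.5,
                         noise_c = 0.03, seed = 65,
                         outlier_spec = list(bad_frame_rate = 0.1,
                                             noisy = 0.25),
                         sigma_model = "counting")
  res <- run_rejection_cycles(sim$datasets, pgr,
                              list(seed = 9, max_cycles = 1))
  expect_gt(nrow(res$log$cycle1$rejected_frames), 0)
  expect_null(res$log$cycle2)
  expect_length(res$datasets, 8 - length(res$log$cycle1$dropped_datasets))
})

test_that("both outlier classes are removed in their designated cycles", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 12,
                         completeness_per_wedge = 0.5, noise_c = 0.02,
                         sigma_model = "counting", seed = 66,
                         outlier_spec = list(bad_frame_rate = 0.1,
                                             nonisomorphous = 0.1))
  res <- run_rejection_cycles(sim$datasets, pgr,
                              list(seed = 9,
                                   reject_datasets = c("R", "b")))
  expect_gt(nrow(res$log$cycle1$rejected_frames), 0)
  bad_ids <- sim$truth_table[outlier == "nonisomorphous", id]
  kept_ids <- vapply(res$datasets, function(d) d$id, character(1))
  expect_false(any(bad_ids %in% kept_ids))
  ## rejection improves fidelity over the no-rejection baseline
  base <- run_rejection_cycles(sim$datasets, pgr,
                               list(seed = 9, reject_frames = "none",
                                    reject_datasets = character(0),
                                    reject_sd = Inf))
  expect_gt(merged_truth_cc(res$merged, truth),
            merged_truth_cc(base$merged, truth))
  ## monotone bookkeeping: surviving count never increases
  expect_lte(res$log$cycle2$surviving, res$log$cycle1$surviving)
})

test_that("reject_bad_datasets never returns an empty cohort", {
  metrics <- data.table::data.table(
    dataset = paste0("d", 1:4),
    a = 1, b = c(0.1, 0.2, 0.15, 0.18), ab = 0.1,
    B = c(0, 40, 80, 120), R = 0.1, cc = c(0.9, 0.8, 0.7, 0.6))
  ## degenerate: force everything out with a zero-width fence by
  ## making every value extreme relative to the rest
  rb <- reject_bad_datasets(metrics, criteria = c("b", "B"), k = 0)
  expect_gt(length(rb$kept_ids), 0)
})
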