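pgc <- point_group("222")

## two-dataset pool where the second is an exactly scaled copy of the
## first
scaled_pair <- function(k2 = 2, B2 = 0, truth = small_truth(), seed = 41,
                        completeness = 0.6) {
  sim <- simulate_wedges(truth, n_datasets = 1,
                         completeness_per_wedge = completeness,
                         noise_c = 0, k_range = c(1, 1), b_range = c(0, 0),
                         seed = seed)
  a <- sim$datasets[[1]]
  b <- a; b$id <- "ds002"
  r <- data.table::copy(b$reflections)
  d <- d_spacing(cbind(r$h, r$k, r$l), b$cell)
  g <- k2 * exp(-2 * B2 / (4 * d^2))
  r[, I := I * g]; r[, sigma := sigma * g]
  b$reflections <- r
  list(a = a, b = b)
}

test_that("batch assignment follows frames/degrees and auto modes", {
  ds <- wedge_dataset("w", unit_cell(20, 30, 40, 90, 90, 90),
                      data.frame(h = 1, k = 1, l = 1, I = 1, sigma = 1,
                                 frame = 1),
                      frame_start = 1, frame_end = 30, deg_per_frame = 0.1)
  ## 30 frames at 0.1 deg/frame with 1 degree per batch -> 3 batches of 10
  b <- assign_batches(ds, degrees_per_batch = 1)
  expect_equal(unname(table(b)), c(10L, 10L, 10L), ignore_attr = TRUE)
  expect_equal(max(b), 3L)
  expect_equal(max(assign_batches(ds)), 1L)            # auto: one batch
  expect_equal(max(assign_batches(ds, frames_per_batch = 7)), 5L)
  expect_error(assign_batches(ds, degrees_per_batch = -1), "positive")
  expect_error(assign_batches(ds, frames_per_batch = 5,
                              degrees_per_batch = 1), "only one")
})

test_that("reference choice uses median B early and smallest B finally", {
  expect_equal(choose_reference(c("x", "y", "z"), c(10, 20, 30), "early"), "y")
  expect_equal(choose_reference(c("x", "y", "z"), c(10, 20, 30), "final"), "x")
  ## lower median on even count
  expect_equal(choose_reference(c("x", "y", "z", "w"), c(10, 20, 30, 40),
                                "early"), "y")
  expect_equal(choose_reference("solo", 5, "final"), "solo")
})

test_that("a doubled dataset is recovered with k = 2 exactly", {
  p <- scaled_pair(k2 = 2, B2 = 0)
  obs <- wedgemerge:::pool_observations(list(p$a, p$b), pgc)
  sc <- scale_datasets(obs, reference_id = "ds001")
  kb <- sc$batches[dataset == "ds002"]
  expect_equal(kb$k, 2, tolerance = 1e-4)
  expect_equal(kb$B, 0, tolerance = 1e-4)
  expect_equal(sc$batches[dataset == "ds001", k], 1)
  ## scaled values of the copy reproduce the original intensities
  scaled <- wedgemerge:::apply_scaling(obs, sc)
  m <- merge(scaled[dataset == "ds001", .(key, I1 = Isc)],
             scaled[dataset == "ds002", .(key, I2 = Isc)], by = "key")
  expect_equal(m$I2, m$I1, tolerance = 1e-4)
})

test_that("injected per-dataset k and B are recovered from noisy data", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 8,
                         completeness_per_wedge = 0.5, noise_c = 0.01,
                         k_range = c(0.5, 2), b_range = c(0, 30), seed = 43)
  obs <- wedgemerge:::pool_observations(sim$datasets, pgc)
  ref_id <- sim$truth_table$id[1]
  sc <- scale_datasets(obs, reference_id = ref_id)
  got <- sc$batches[order(dataset)]
  tt <- sim$truth_table[order(id)]
  ## identifiability: scales are relative to the reference dataset
  k_rel_true <- tt$k / tt$k[tt$id == ref_id]
  b_rel_true <- tt$B - tt$B[tt$id == ref_id]
  expect_equal(got$k, k_rel_true, tolerance = 0.05)
  expect_true(all(abs(got$B - b_rel_true) < 2))
})

test_that("a single dataset keeps k = 1, B = 0", {
  p <- scaled_pair()
  obs <- wedgemerge:::pool_observations(list(p$a), pgc)
  sc <- scale_datasets(obs, reference_id = "ds001")
  expect_equal(sc$batches$k, 1)
  expect_equal(sc$batches$B, 0)
})

test_that("error model recovers counting-only and inflated noise", {
  truth <- small_truth()
  ## pure counting noise: a near 1, b near 0
  sim <- simulate_wedges(truth, n_datasets = 6,
                         completeness_per_wedge = 0.6, noise_c = 0,
                         k_range = c(1, 1), b_range = c(0, 0), seed = 44)
  obs <- wedgemerge:::pool_observations(sim$datasets, pgc)
  sc <- scale_datasets(obs, "ds001")
  scaled <- wedgemerge:::apply_scaling(obs, sc)
  em <- refine_error_model(scaled, "ds002")
  expect_true(em$ok)
  expect_gt(em$a, 0.8); expect_lt(em$a, 1.2)
  expect_lte(em$b, 1e-3)
  ## 5% proportional noise beyond the reported counting sigma:
  ## b recovered near 0.05^2 = 0.0025
  sim2 <- simulate_wedges(truth, n_datasets = 6,
                          completeness_per_wedge = 0.6, noise_c = 0.05,
                          k_range = c(1, 1), b_range = c(0, 0),
                          sigma_model = "counting", seed = 45)
  obs2 <- wedgemerge:::pool_observations(sim2$datasets, pgc)
  sc2 <- scale_datasets(obs2, "ds001")
  em2 <- refine_error_model(wedgemerge:::apply_scaling(obs2, sc2), "ds002")
  expect_gt(em2$b, 0.0025 / 2)
  expect_lt(em2$b, 0.0025 * 2)
  ## insufficient observations: flagged fallback
  tiny <- scaled[dataset == "ds002"][1:10]
  em3 <- refine_error_model(tiny, "ds002")
  expect_false(em3$ok)
  expect_equal(c(em3$a, em3$b), c(1, 0))
})

test_that("merging averages duplicates and rejects gross outliers", {
  ## hand-built observation table: 3 unique reflections
  mkobs <- function(keyv, I, sig, ds = "d1") {
    data.table::as.data.table(list(
      dataset = ds, frame = 1L, batch = 1L, gbatch = paste0(ds, "#1"),
      key = keyv, sign = 1L, I = I, sigma = sig, d = 3, s2 = 1 / 36,
      k = 1, B = 0, g = 1, Isc = I, sigsc = sig))
  }
  dup <- mkobs(rep(1e6, 4), rep(100, 4), rep(10, 4))
  m1 <- merge_observations(dup)
  expect_equal(m1$table$Imean, 100)
  expect_equal(m1$table$mult, 4L)
  expect_equal(m1$table$sigma, 10 / 2)   # sigma / sqrt(multiplicity)
  ## one 10-sigma outlier among 8 gets rejected
  out <- mkobs(rep(2e6, 8), c(rep(100, 7), 100 + 10 * 5), rep(5, 8))
  m2 <- merge_observations(out)
  expect_equal(m2$n_rejected, 1L)
  expect_equal(m2$table[key == 2e6, mult], 7L)
  expect_equal(m2$table[key == 2e6, Imean], 100)
  ## equal weights reduce to the arithmetic mean
  eq <- mkobs(rep(3e6, 3), c(90, 100, 110), rep(8, 3))
  m3 <- merge_observations(eq)
  expect_equal(m3$table$Imean, 100)
})

test_that("shell statistics behave on exact duplicate observations", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 1, completeness_per_wedge = 1,
                         noise_c = 0, k_range = c(1, 1), b_range = c(0, 0),
                         seed = 46)
  a <- sim$datasets[[1]]
  b <- a; b$id <- "ds002"
  obs <- wedgemerge:::pool_observations(list(a, b), pgc)
  sc <- scale_datasets(obs, "ds001")
  merged <- merge_observations(wedgemerge:::apply_scaling(obs, sc))
  st <- shell_statistics(merged, truth$cell, pgc, n_shells = 5, seed = 2)
  overall <- st[is.na(shell)]
  ## every unique reflection observed twice with identical values
  expect_equal(overall$cc_half, 1, tolerance = 1e-12)
  expect_equal(overall$rmeas, 0, tolerance = 1e-12)
  expect_equal(overall$multiplicity, 2, tolerance = 0.01)
  ## full coverage: 100% complete, and shell uniques sum to the overall
  expect_equal(overall$completeness, 100, tolerance = 0.5)
  expect_equal(sum(st[!is.na(shell), n_unique]), overall$n_unique)
  expect_true(all(st$completeness <= 100 + 1e-9))
})

test_that("CC1/2 matches the closed-form signal/noise expectation", {
  ## truth variance vs noise-of-half-mean variance, 10 seeds
  truth <- small_truth()
  devs <- vapply(1:10, function(sd_i) {
    sim <- simulate_wedges(truth, n_datasets = 4,
                           completeness_per_wedge = 0.8,
                           noise_c = 0.35, k_range = c(1, 1),
                           b_range = c(0, 0), seed = 400 + sd_i)
    obs <- wedgemerge:::pool_observations(sim$datasets, pgc)
    sc <- scale_datasets(obs, "ds001")
    scaled <- wedgemerge:::apply_scaling(obs, sc)
    merged <- merge_observations(scaled, reject_sd = Inf)
    st <- shell_statistics(merged, truth$cell, pgc, n_shells = 4,
                           seed = sd_i)
    ## closed form per overall set: var(signal) / (var(signal) +
    ## mean per-half noise variance of the half means)
    kept <- merged$observations[kept == TRUE]
    kept[, m := .N, by = key]
    kept <- kept[m >= 2]
    sig_var <- stats::var(kept[, .(mu = mean(Isc)), by = key]$mu)
    noise_half <- kept[, .(v = mean(sigsc^2) / ceiling(.N / 2)), by = key]
    expected <- sig_var / (sig_var + mean(noise_half$v))
    st[is.na(shell), cc_half] - expected
  }, numeric(1))
  expect_lt(mean(abs(devs)), 0.1)
})

test_that("anomalous merging separates Friedel mates and CCano sees signal", {
  truth <- generate_truth(unit_cell(30, 40, 50, 90, 90, 90),
                          point_group("222"), d_min = 3.5, wilson_b = 10,
                          anomalous_fraction = 0.3, seed = 47)
  sim <- simulate_wedges(truth, n_datasets = 10,
                         completeness_per_wedge = 0.8, noise_c = 0.01,
                         k_range = c(1, 1), b_range = c(0, 0),
                         anomalous = TRUE, seed = 48)
  obs <- wedgemerge:::pool_observations(sim$datasets, pgc, anomalous = TRUE)
  sc <- scale_datasets(obs, "ds001")
  merged <- merge_observations(wedgemerge:::apply_scaling(obs, sc),
                               anomalous = TRUE)
  expect_false(is.null(merged$anom))
  st <- shell_statistics(merged, truth$cell, pgc, n_shells = 4, seed = 3)
  expect_true(is.finite(st[is.na(shell), cc_ano]))
  expect_gt(st[is.na(shell), cc_ano], 0.2)
})

test_that("anisotropy curves agree for isotropic data and split when forced", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 6, completeness_per_wedge = 0.7,
                         noise_c = 0.05, k_range = c(1, 1), b_range = c(0, 0),
                         seed = 49)
  obs <- wedgemerge:::pool_observations(sim$datasets, pgc)
  sc <- scale_datasets(obs, "ds001")
  merged <- merge_observations(wedgemerge:::apply_scaling(obs, sc))
  iso <- anisotropy_cc(merged, truth$cell, n_bins = 3, seed = 4)
  cur <- iso$curves[!is.na(cc_half)]
  spread <- cur[, .(spread = max(cc_half) - min(cc_half)), by = bin]
  expect_true(all(spread$spread < 0.15))
  ## inject anisotropy along c*: the c*-cone signal is replaced by
  ## fresh noise (each wedge independently), which decorrelates the
  ## half-sets there while a* stays intact
  damped <- wedgemerge:::with_seed(77, lapply(sim$datasets, function(ds) {
    r <- data.table::copy(ds$reflections)
    frac_l <- abs(r$l / 50) / pmax(sqrt((r$h / 30)^2 + (r$k / 40)^2 +
                                          (r$l / 50)^2), 1e-9)
    f <- as.numeric(frac_l < 0.7)   # keep only off-cone signal
    r[, I := I * f + (1 - f) * stats::rnorm(.N, mean(abs(I)), mean(abs(I)))]
    ds$reflections <- r
    ds
  }))
  obs2 <- wedgemerge:::pool_observations(damped, pgc)
  sc2 <- scale_datasets(obs2, "ds001")
  merged2 <- merge_observations(wedgemerge:::apply_scaling(obs2, sc2))
  ani <- anisotropy_cc(merged2, truth$cell, n_bins = 3, seed = 4)
  sum_iso <- iso$summary; sum_ani <- ani$summary
  ## the c* axis drops relative to a*
  drop_c <- sum_iso[axis == "c*", cc_half] - sum_ani[axis == "c*", cc_half]
  drop_a <- sum_iso[axis == "a*", cc_half] - sum_ani[axis == "a*", cc_half]
  expect_gt(drop_c, drop_a)
  ## degenerate input: only 00l reflections -> other axes flagged
  only_l <- wedge_dataset("z", truth$cell,
                          data.frame(h = 0, k = 0, l = 2:9,
                                     I = 100, sigma = 1, frame = 1))
  obs3 <- wedgemerge:::pool_observations(list(only_l, only_l), pgc)
  obs3[, `:=`(k = 1, B = 0, g = 1, Isc = I, sigsc = sigma)]
  m3 <- merge_observations(obs3)
  a3 <- anisotropy_cc(m3, truth$cell, n_bins = 1, seed = 5)
  expect_true(all(a3$curves[axis != "c*", flagged]))
})

test_that("merged output file has the multiplicity column", {
  p <- scaled_pair()
  obs <- wedgemerge:::pool_observations(list(p$a, p$b), pgc)
  sc <- scale_datasets(obs, "ds001")
  merged <- merge_observations(wedgemerge:::apply_scaling(obs, sc))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_merged(merged, path)
  tab <- utils::read.delim(path)
  expect_true("multiplicity" %in% names(tab))
  expect_equal(nrow(tab), nrow(merged$table))
})
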