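pg1 <- point_group("1")

test_that("Wilson B estimation recovers the generating falloff", {
  truth <- generate_truth(unit_cell(30, 40, 50, 90, 90, 90),
                          point_group("222"), d_min = 2.2, wilson_b = 20,
                          seed = 31)
  sim <- simulate_wedges(truth, n_datasets = 1, completeness_per_wedge = 0.9,
                         noise_c = 0.02, k_range = c(1, 1), b_range = c(0, 0),
                         seed = 4)
  est <- estimate_wilson_b(sim$datasets[[1]])
  expect_true(est$ok)
  expect_lt(abs(est$wilson_b - 20) / 20, 0.10)
})

test_that("flat intensities give a near-zero B and offsets shift by delta B", {
  truth <- generate_truth(unit_cell(30, 40, 50, 90, 90, 90),
                          point_group("222"), d_min = 2.2, wilson_b = 0,
                          seed = 32)
  sim0 <- simulate_wedges(truth, n_datasets = 2, completeness_per_wedge = 0.9,
                          noise_c = 0.02, k_range = c(1, 1),
                          b_range = c(0, 0), seed = 5)
  e0 <- estimate_wilson_b(sim0$datasets[[1]])
  ## near zero relative to the typical 10-30 A^2 range; the estimator's
  ## own sampling noise on ~700 reflections/bin is about 1 A^2
  expect_lt(abs(e0$wilson_b), 2.5)
  ## same truth, one dataset with an extra exp(-2 dB s^2) falloff
  simB <- simulate_wedges(truth, n_datasets = 2, completeness_per_wedge = 0.9,
                          noise_c = 0.02, k_range = c(1, 1),
                          b_range = c(12, 12), seed = 5)
  eB <- estimate_wilson_b(simB$datasets[[1]])
  dB <- eB$wilson_b - e0$wilson_b
  expect_lt(abs(dB - 12) / 12, 0.10)
})

test_that("distance metric arithmetic and bounds", {
  ## d = sqrt(1 - CC): CC = 0.84 -> 0.4
  expect_equal(sqrt(1 - 0.84), 0.4)
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 4, completeness_per_wedge = 0.5,
                         noise_c = 0.03, seed = 6)
  dm <- cc_distance_matrix(sim$datasets, truth$pg)
  expect_equal(diag(dm$dist), rep(0, 4), ignore_attr = TRUE)
  expect_equal(dm$dist, t(dm$dist))
  expect_true(all(dm$dist >= 0 & dm$dist <= sqrt(2) + 1e-12))
  ## identical datasets at distance ~0
  dm2 <- cc_distance_matrix(list(sim$datasets[[1]],
                                 { d <- sim$datasets[[1]]; d$id <- "copy"; d }),
                            truth$pg)
  expect_lt(dm2$dist[1, 2], 1e-6)
})

test_that("datasets below min_common against everyone are excluded", {
  mk <- function(id, hs, I) {
    wedge_dataset(id, unit_cell(20, 30, 40, 90, 90, 90),
                  data.frame(h = hs, k = 0, l = 0, I = I, sigma = 1,
                             frame = 1))
  }
  a <- mk("a", 1:10, (1:10) * 10)
  b <- mk("b", 1:10, (1:10) * 10 + 5)
  c <- mk("c", c(1, 2, 15), c(10, 20, 30))  # only 2 common reflections
  dm <- cc_distance_matrix(list(a, b, c), pg1, min_common = 3)
  expect_equal(dm$excluded$id, "c")
  expect_setequal(dm$ids, c("a", "b"))
  ## fewer than 2 survivors is a hard error
  expect_error(cc_distance_matrix(list(a, mk("d", 21:25, 1:5)), pg1),
               "fewer than 2")
})

test_that("|E|^2 normalization has unit per-shell mean", {
  with_seed <- wedgemerge:::with_seed
  with_seed(7, {
    d <- stats::runif(2000, 2, 20)
    I <- stats::rexp(2000) * exp(-0.1 / d^2)
    e2 <- wedgemerge:::normalize_e2(I, d, n_bins = 8)
    s2 <- 1 / (4 * d^2)
    qs <- unique(stats::quantile(s2, probs = seq(0, 1, length.out = 9)))
    bin <- cut(s2, qs, include.lowest = TRUE)
    means <- tapply(e2, bin, mean)
    expect_equal(as.numeric(means), rep(1, length(means)), tolerance = 1e-6)
  })
})

test_that("two isomorph classes are recovered at the 2-cluster cut", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 12,
                         completeness_per_wedge = 0.4, noise_c = 0.05,
                         n_clusters = 2, cluster_perturbation = 0.45,
                         seed = 8)
  dm <- cc_distance_matrix(sim$datasets, truth$pg)
  tree <- hierarchical_cluster(dm, sim$datasets)
  labels <- stats::cutree(tree$hc, k = 2)
  names(labels) <- tree$ids
  ev <- evaluate_against_truth(sim, cluster_labels = labels)
  expect_equal(ev$cluster_ari, 1.0)
  ## dendrogram conservation: leaves of the root = all datasets
  root <- tree$nodes[which.max(tree$nodes$n_members)]
  expect_setequal(root$members[[1]], tree$ids)
  ## heights non-decreasing
  expect_true(all(diff(tree$hc$height) >= -1e-9))
})

test_that("cluster trees export to Newick with all leaves present", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 5, completeness_per_wedge = 0.5,
                         seed = 13)
  dm <- cc_distance_matrix(sim$datasets, truth$pg)
  tree <- hierarchical_cluster(dm)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  nwk <- readLines(path)
  for (id in tree$ids) expect_match(nwk, id, fixed = TRUE)
})

test_that("three leaves give exactly two internal nodes", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 3, completeness_per_wedge = 0.5,
                         seed = 9)
  dm <- cc_distance_matrix(sim$datasets, truth$pg)
  tree <- hierarchical_cluster(dm)
  expect_equal(nrow(tree$nodes), 2)
})

test_that("LCV matches a direct formula computation", {
  c1 <- unit_cell(30, 40, 50, 90, 90, 90)
  expect_equal(lcv_percent(list(c1, c1, c1)), 0)
  c2 <- unit_cell(30.3, 40, 50, 90, 90, 90)  # +1% in a
  got <- lcv_percent(list(c1, c2))
  ## direct: face diagonals of both cells, max relative spread
  diag_of <- function(x, y) sqrt(x^2 + y^2)   # 90 degree faces
  spread <- function(v) (max(v) - min(v)) / min(v)
  want <- 100 * max(spread(c(diag_of(30, 40), diag_of(30.3, 40))),
                    spread(c(diag_of(40, 50), diag_of(40, 50))),
                    spread(c(diag_of(30, 50), diag_of(30.3, 50))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("cell clustering separates cell-shifted classes", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 10,
                         completeness_per_wedge = 0.3,
                         n_clusters = 2, cluster_cell_shift = 0.02,
                         cell_jitter_rel = 0.002, seed = 10)
  tree <- cell_cluster(sim$datasets)
  labels <- stats::cutree(tree$hc, k = 2)
  names(labels) <- tree$ids
  ev <- evaluate_against_truth(sim, cluster_labels = labels)
  expect_equal(ev$cluster_ari, 1.0)
  ## identical cells: all LCV zero
  sim0 <- simulate_wedges(truth, n_datasets = 4,
                          completeness_per_wedge = 0.3, seed = 11)
  tree0 <- cell_cluster(sim0$datasets)
  expect_true(all(tree0$nodes$lcv < 1e-9))
})

test_that("cell prefilter rejects deviant cells and is median-stable", {
  mk <- function(id, a) {
    wedge_dataset(id, unit_cell(a, 40, 50, 90, 90, 90),
                  data.frame(h = 1, k = 2, l = 3, I = 1, sigma = 1,
                             frame = 1))
  }
  ds <- c(lapply(1:6, function(i) mk(paste0("d", i), 30 + 0.01 * i)),
          list(mk("out", 30 * 1.15)))
  pf <- prefilter_cells(ds, tol_len = 0.1)
  expect_equal(pf$rejected$id, "out")
  expect_length(pf$kept, 6)
  ## re-running on the kept set rejects nothing new
  pf2 <- prefilter_cells(pf$kept, tol_len = 0.1)
  expect_equal(nrow(pf2$rejected), 0)
  ## all identical: nothing rejected
  same <- lapply(1:4, function(i) mk(paste0("s", i), 30))
  expect_equal(nrow(prefilter_cells(same)$rejected), 0)
})

test_that("cluster candidates respect completeness/multiplicity thresholds", {
  truth <- small_truth()
  sim <- simulate_wedges(truth, n_datasets = 10,
                         completeness_per_wedge = 0.5, noise_c = 0.03,
                         seed = 12)
  dm <- cc_distance_matrix(sim$datasets, truth$pg)
  tree <- hierarchical_cluster(dm, sim$datasets)
  cand <- select_cluster_candidates(tree, sim$datasets, truth$pg)
  ## the root pools 10 half-complete wedges: complete and redundant
  expect_gte(nrow(cand), 1)
  expect_equal(cand$n_members[1], 10)
  expect_gte(cand$completeness[1], 0.9)
  expect_gte(cand$multiplicity[1], 2)
  ## impossible thresholds: empty with a warning
  expect_warning(
    none <- select_cluster_candidates(tree, sim$datasets, truth$pg,
                                      completeness_min = 1.01),
    "no cluster")
  expect_equal(nrow(none), 0)
  ## zero thresholds keep every internal node
  all_nodes <- select_cluster_candidates(tree, sim$datasets, truth$pg,
                                         completeness_min = 0,
                                         multiplicity_min = 0)
  expect_equal(nrow(all_nodes), nrow(tree$nodes))
})
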