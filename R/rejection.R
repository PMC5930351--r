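## Frame-level and dataset-level outlier rejection over merge cycles.

#' Per-frame correlation against the merged reference
#'
#' Pearson CC between the scaled observations of each (dataset, frame)
#' and the merged intensities at the same unique reflections. Frames
#' with fewer than 3 matched observations are flagged low-evidence and
#' are never auto-rejected.
#'
#' @param obs_scaled Scaled observation table (from `apply_scaling`);
#'   only used for its identity, the reference comes from the merged
#'   observation map.
#' @param merged A `merged_dataset`.
#' @return data.table (dataset, frame, cc, n, low_evidence).
#' @export
per_frame_cc <- function(obs_scaled, merged) {
  ## leave-self-out reference: each observation is compared against the
  ## weighted mean of the *other* kept observations of its reflection,
  ## so a corrupt frame cannot vouch for itself through the merge
  dt <- data.table::copy(merged$observations)
  dt[, `:=`(Wk = sum(w[kept]), Mk = sum((w * Isc)[kept])), by = key]
  dt[, Iref := ifelse(kept, (Mk - w * Isc) / (Wk - w), Mk / Wk)]
  dt <- dt[is.finite(Iref)]
  out <- dt[, {
    n <- .N
    cc <- if (n >= 3 && stats::sd(Isc) > 0 && stats::sd(Iref) > 0) {
      stats::cor(Isc, Iref)
    } else NA_real_
    list(cc = cc, n = n)
  }, by = .(dataset, frame)]
  out[, low_evidence := n < 3]
  out[]
}

#' Remove bad frames from datasets
#'
#' Flags frames whose CC against the merged reference falls below
#' either the Tukey lower fence (Q1 - 1.5 IQR over the cohort's frame
#' CCs) or an absolute threshold, and strips their observations.
#' Low-evidence frames (< 3 matched observations) are kept. A dataset
#' reduced below `min_obs_frac` of its original observation count is
#' dropped entirely.
#'
#' @param datasets List of [wedge_dataset()]s.
#' @param frame_ccs Result of [per_frame_cc()].
#' @param mode "tukey" or a numeric absolute CC threshold.
#' @param k Tukey fence multiplier.
#' @param min_obs_frac Survival fraction below which a dataset is
#'   dropped.
#' @return List with `datasets` (trimmed), `rejected_frames`
#'   (data.table dataset/frame/cc/threshold), `dropped_datasets`.
#' @export
reject_bad_frames <- function(datasets, frame_ccs, mode = "tukey", k = 1.5,
                              min_obs_frac = 0.2) {
  fc <- data.table::copy(frame_ccs)
  if (identical(mode, "none")) {
    fc[, flag := FALSE]
    thr <- -Inf
  } else if (is.numeric(mode)) {
    thr <- mode
    fc[, flag := !low_evidence & is.finite(cc) & cc < thr]
  } else {
    ## Tukey fence on the Fisher z scale: correlations near 1 are
    ## heavily left-skewed, and fencing atanh(cc) keeps the
    ## false-positive rate down without losing recall
    z <- atanh(pmin(pmax(fc[!(low_evidence)]$cc, -0.999), 0.999))
    tf <- tukey_lower_fence(z, k)
    thr <- tanh(tf$threshold)
    fc[, flag := FALSE]
    fc[!(low_evidence), flag := tf$flags]
  }
  rejected <- fc[flag == TRUE, .(dataset, frame, cc, threshold = thr)]
  dropped <- character(0)
  out <- list()
  for (ds in datasets) {
    bad <- rejected[dataset == ds$id, frame]
    if (length(bad) == 0) {
      out[[length(out) + 1]] <- ds
      next
    }
    r <- ds$reflections
    kept <- r[!(frame %in% bad)]
    if (nrow(kept) < min_obs_frac * nrow(r)) {
      dropped <- c(dropped, ds$id)
      next
    }
    ds$reflections <- kept
    out[[length(out) + 1]] <- ds
  }
  list(datasets = out, rejected_frames = rejected,
       dropped_datasets = dropped)
}

#' Per-dataset quality metrics for outlier screening
#'
#' For every dataset: the error-model parameters `a`, `b` and their
#' product `ab`; `B`, the observation-weighted mean scaling B of its
#' batches; `R`, the merging residual sum |I_scaled - <I>| / sum <I>
#' over the dataset's observations; and `cc`, the correlation of its
#' scaled intensities with the merged values.
#'
#' @param obs_scaled Scaled observations.
#' @param merged A `merged_dataset`.
#' @param scaling A `scaling_model`.
#' @param error_models Named list of per-dataset error models.
#' @return data.table (dataset, a, b, ab, B, R, cc).
#' @export
dataset_quality_metrics <- function(obs_scaled, merged, scaling,
                                    error_models) {
  dt <- data.table::copy(obs_scaled)
  dt[merged$table, on = "key", Iref := i.Imean]
  dt <- dt[is.finite(Iref)]
  nb <- dt[, .(n = .N), by = .(dataset, gbatch)]
  nb[scaling$batches, on = "gbatch", B := i.B]
  bmean <- nb[, .(B = sum(B * n) / sum(n)), by = dataset]
  per <- dt[, {
    cc <- if (.N >= 3 && stats::sd(Isc) > 0 && stats::sd(Iref) > 0) {
      stats::cor(Isc, Iref)
    } else NA_real_
    list(R = sum(abs(Isc - Iref)) / max(sum(abs(Iref)), 1e-12), cc = cc)
  }, by = dataset]
  per[bmean, on = "dataset", B := i.B]
  per[, `:=`(a = 1, b = 0)]
  for (id in names(error_models)) {
    per[dataset == id, `:=`(a = error_models[[id]]$a,
                            b = error_models[[id]]$b)]
  }
  per[, ab := a * b]
  per[, .(dataset, a, b, ab, B, R, cc)]
}

#' Reject datasets with extreme quality metrics
#'
#' Applies two-sided Tukey 1.5 IQR fences per chosen metric (the
#' default screens `b` and `B`), except `cc` which uses a lower fence
#' only; the union of flags is rejected. If everything would be
#' rejected, the best-cc half is kept instead and an error is logged.
#'
#' @param metrics From [dataset_quality_metrics()].
#' @param criteria Subset of c("b", "ab", "B", "R", "cc").
#' @param k Fence multiplier.
#' @return List with `kept_ids`, `rejected` (data.table
#'   dataset/metric/value/fence_low/fence_high), `note`.
#' @export
reject_bad_datasets <- function(metrics, criteria = c("b", "B"), k = 1.5) {
  flags <- rep(FALSE, nrow(metrics))
  rejected <- list()
  for (cr in criteria) {
    v <- metrics[[cr]]
    if (sum(is.finite(v)) < 4) next
    f <- tukey_fences(v, k)
    bad <- if (cr == "cc") is.finite(v) & v < f$lower
           else is.finite(v) & (v < f$lower | v > f$upper)
    if (any(bad)) {
      rejected[[length(rejected) + 1]] <- data.table::data.table(
        dataset = metrics$dataset[bad], metric = cr, value = v[bad],
        fence_low = f$lower, fence_high = f$upper)
    }
    flags <- flags | bad
  }
  note <- NULL
  if (all(flags)) {
    keep_n <- ceiling(nrow(metrics) / 2)
    ord <- order(-metrics$cc)
    flags <- rep(TRUE, nrow(metrics))
    flags[ord[seq_len(keep_n)]] <- FALSE
    note <- "all datasets flagged; kept the best-cc half instead"
  }
  list(kept_ids = metrics$dataset[!flags],
       rejected = if (length(rejected)) data.table::rbindlist(rejected)
                  else data.table::data.table(),
       note = note)
}

default_merge_config <- function() {
  list(frames_per_batch = NULL, degrees_per_batch = NULL,
       anomalous = FALSE, reject_frames = "tukey",
       reject_datasets = c("b", "B"), max_cycles = 3L,
       min_obs_frac = 0.2, n_shells = 10L, seed = 1L,
       d_min = NULL, d_max = NULL, reject_sd = 4, min_common = 3)
}

scale_and_merge_once <- function(datasets, pg, config, stage) {
  wb <- vapply(datasets, function(d) estimate_wilson_b(d)$wilson_b, numeric(1))
  ids <- vapply(datasets, function(d) d$id, character(1))
  ref <- choose_reference(ids, wb, stage)
  obs <- pool_observations(datasets, pg, anomalous = config$anomalous,
                           frames_per_batch = config$frames_per_batch,
                           degrees_per_batch = config$degrees_per_batch)
  if (!is.null(config$d_min)) obs <- obs[d >= config$d_min]
  if (!is.null(config$d_max)) obs <- obs[d <= config$d_max]
  scaling <- scale_datasets(obs, ref)
  scaled <- apply_scaling(obs, scaling)
  ## pre-merge whose robust rejection screens gross corruption before
  ## (a, b) refinement; otherwise corrupt observations poison the
  ## leave-one-out references. The screening variance carries an
  ## intensity-proportional floor (b = 0.01) so that systematic errors
  ## of a few percent of I -- exactly what the error model must still
  ## be able to measure -- survive, while uncorrelated junk does not
  floor_ems <- stats::setNames(
    rep(list(list(a = 1, b = 0.01)), length(ids)), ids)
  pre <- merge_observations(scaled, floor_ems, anomalous = config$anomalous,
                            reject_sd = 8)
  clean <- pre$observations[kept == TRUE]
  ems <- refine_error_models(clean, setdiff(ids, scaling$unscalable))
  merged <- merge_observations(scaled, ems, anomalous = config$anomalous,
                               reject_sd = config$reject_sd)
  list(obs = obs, scaled = scaled, scaling = scaling, error_models = ems,
       merged = merged, reference = ref, wilson_b = stats::setNames(wb, ids))
}

#' Merge a cluster with iterative outlier rejection
#'
#' Up to three cycles: (1) scale and merge all datasets (median-B
#' reference) and reject bad frames; (2) rescale and remerge without
#' the bad frames and reject bad datasets; (3) final scaling against
#' the smallest-B dataset, merge, and shell statistics. A cycle that
#' rejects nothing stops the iteration early (the final merge is still
#' performed).
#'
#' @param datasets Cluster members (>= 2 consistently indexed
#'   [wedge_dataset()]s).
#' @param pg Merging [point_group()].
#' @param config List of options, see `default_merge_config()`:
#'   notably `reject_frames` ("tukey", "none" or an absolute CC),
#'   `reject_datasets` (metric subset), `max_cycles`,
#'   `degrees_per_batch`/`frames_per_batch`, `anomalous`, `n_shells`,
#'   `seed`, `d_min`/`d_max`.
#' @return List with `merged` (final `merged_dataset`), `stats`
#'   (`shell_stats`), `log` (per-cycle rejection log), `scaling`,
#'   `error_models`, `datasets` (survivors), `n_merges`.
#' @export
run_rejection_cycles <- function(datasets, pg, config = list()) {
  config <- utils::modifyList(default_merge_config(), config)
  if (length(datasets) < 2) stop("need at least 2 datasets in the cluster")
  log <- list()
  n_merges <- 0L

  ## cycle 1: merge everything, screen frames
  cyc1 <- scale_and_merge_once(datasets, pg, config, "early")
  n_merges <- n_merges + 1L
  n_frame_rej <- 0L
  if (!identical(config$reject_frames, "none")) {
    fcc <- per_frame_cc(cyc1$scaled, cyc1$merged)
    fr <- reject_bad_frames(datasets, fcc, mode = config$reject_frames,
                            min_obs_frac = config$min_obs_frac)
    n_frame_rej <- nrow(fr$rejected_frames)
    log$cycle1 <- list(rejected_frames = fr$rejected_frames,
                       dropped_datasets = fr$dropped_datasets,
                       surviving = length(fr$datasets))
    datasets <- fr$datasets
    if (length(datasets) < 2) {
      stop("fewer than 2 datasets survive frame rejection")
    }
  } else {
    log$cycle1 <- list(rejected_frames = data.table::data.table(),
                       dropped_datasets = character(0),
                       surviving = length(datasets))
  }

  ## cycle 2: remerge, screen datasets (only when something changed and
  ## the budget allows)
  last <- cyc1
  if (config$max_cycles >= 2 && n_frame_rej > 0 &&
      length(config$reject_datasets) > 0) {
    cyc2 <- scale_and_merge_once(datasets, pg, config, "early")
    n_merges <- n_merges + 1L
    metrics <- dataset_quality_metrics(cyc2$scaled, cyc2$merged,
                                       cyc2$scaling, cyc2$error_models)
    rb <- reject_bad_datasets(metrics, config$reject_datasets)
    log$cycle2 <- list(metrics = metrics, rejected_datasets = rb$rejected,
                       note = rb$note, surviving = length(rb$kept_ids))
    datasets <- Filter(function(d) d$id %in% rb$kept_ids, datasets)
    if (length(datasets) < 2) {
      stop("fewer than 2 datasets survive dataset rejection")
    }
    last <- cyc2
  }

  ## final cycle: smallest-B reference, merge, statistics
  fin <- scale_and_merge_once(datasets, pg, config, "final")
  n_merges <- n_merges + 1L
  cell <- datasets[[1]]$cell
  stats <- shell_statistics(fin$merged, cell, pg,
                            n_shells = config$n_shells, seed = config$seed,
                            d_min = config$d_min, d_max = config$d_max)
  log$final <- list(reference = fin$reference,
                    unscalable = fin$scaling$unscalable,
                    n_obs_rejected = fin$merged$n_rejected,
                    surviving = length(datasets))
  list(merged = fin$merged, stats = stats, log = log,
       scaling = fin$scaling, error_models = fin$error_models,
       datasets = datasets, n_merges = n_merges, reference = fin$reference)
}
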