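## Relative scaling in batches, error-model refinement, merging to
## unique reflections, and per-shell data-quality statistics.
##
## Observation convention: I_obs ~ g * I_true with g = k * exp(-2 B s^2)
## per scaling batch; the scaled value entering the merge is I_obs / g.

#' Assign scaling batches to a wedge
#'
#' A batch is a contiguous run of frames sharing one (scale, B) pair.
#' Exactly one of the three modes is active: a fixed number of frames
#' per batch, a rotation width in degrees per batch (converted via the
#' wedge's degrees-per-frame), or `auto` (one batch per dataset).
#'
#' @param dataset A [wedge_dataset()].
#' @param frames_per_batch,degrees_per_batch Batch size (choose one).
#' @return Integer vector: batch label for each frame from
#'   `frame_start` to `frame_end` (last batch may be short).
#' @export
assign_batches <- function(dataset, frames_per_batch = NULL,
                           degrees_per_batch = NULL) {
  n_frames <- dataset$frame_end - dataset$frame_start + 1L
  if (!is.null(frames_per_batch) && !is.null(degrees_per_batch)) {
    stop("give only one of frames_per_batch and degrees_per_batch")
  }
  fpb <- if (!is.null(frames_per_batch)) {
    frames_per_batch
  } else if (!is.null(degrees_per_batch)) {
    degrees_per_batch / dataset$deg_per_frame
  } else {
    n_frames  # auto: one batch per dataset
  }
  if (fpb <= 0) stop("batch size must be positive")
  fpb <- max(1L, as.integer(round(fpb)))
  as.integer((seq_len(n_frames) - 1L) %/% fpb + 1L)
}

## Pool datasets into one observation table with asymmetric-unit keys,
## per-observation resolution, and global batch labels.
pool_observations <- function(datasets, pg, anomalous = FALSE,
                              frames_per_batch = NULL,
                              degrees_per_batch = NULL) {
  tabs <- lapply(datasets, function(ds) {
    r <- ds$reflections
    hkl <- cbind(r$h, r$k, r$l)
    asu <- map_to_asu(hkl, pg, anomalous = anomalous)
    batches <- assign_batches(ds, frames_per_batch, degrees_per_batch)
    d <- d_spacing(hkl, ds$cell)
    data.table::as.data.table(list(
      dataset = ds$id, frame = r$frame,
      batch = batches[r$frame - ds$frame_start + 1L],
      key = asu$key, sign = asu$sign,
      I = r$I, sigma = r$sigma, d = d, s2 = s2_of_d(d)))
  })
  obs <- data.table::rbindlist(tabs)
  obs[, gbatch := paste(dataset, batch, sep = "#")]
  obs[]
}

#' Choose the scaling reference dataset
#'
#' Early cycles use the dataset with median Wilson B (extremely sharp
#' datasets tend to be outliers and degrade the scaling); the final
#' cycle uses the dataset with the smallest B, i.e. the least
#' intensity falloff.
#'
#' @param ids Dataset ids.
#' @param b_estimates Per-dataset B estimates (same order).
#' @param cycle_stage "early" or "final".
#' @return The chosen dataset id.
#' @export
choose_reference <- function(ids, b_estimates, cycle_stage = c("early", "final")) {
  cycle_stage <- match.arg(cycle_stage)
  stopifnot(length(ids) == length(b_estimates), length(ids) >= 1)
  b <- ifelse(is.finite(b_estimates), b_estimates, stats::median(b_estimates, na.rm = TRUE))
  if (cycle_stage == "final") {
    ids[which.min(b)]
  } else {
    ord <- order(b)
    ids[ord[ceiling(length(ids) / 2)]]  # lower median on even counts
  }
}

#' Scale datasets against a reference
#'
#' Alternating least squares on the log scale: minimise
#' sum (ln I_obs - ln <I_h> - ln k_b + 2 B_b s^2)^2 over strong
#' (I > 3 sigma) observations, alternating between per-batch (k, B)
#' fits and reference intensity updates until the relative objective
#' change drops below `tol`. The reference dataset's batches are
#' pinned at k = 1, B = 0. Datasets with no unique reflections in
#' common with the rest are flagged unscalable and excluded.
#'
#' @param obs Observation table from `pool_observations`.
#' @param reference_id Id of the reference dataset.
#' @param tol Relative objective-change convergence threshold.
#' @param max_iter Iteration cap.
#' @return A `scaling_model`: list with `batches` (data.table dataset,
#'   batch, gbatch, k, B), `unscalable` (ids), `n_iter`, `objective`.
#' @export
scale_datasets <- function(obs, reference_id, tol = 1e-6, max_iter = 50) {
  ids <- unique(obs$dataset)
  ## connectivity: a dataset must share keys with the others
  unscalable <- character(0)
  if (length(ids) > 1) {
    for (id in ids) {
      mine <- unique(obs[dataset == id, key])
      rest <- unique(obs[dataset != id, key])
      if (length(intersect(mine, rest)) == 0) unscalable <- c(unscalable, id)
    }
  }
  work <- obs[!(dataset %in% unscalable) & I > 3 * sigma & I > 0]
  fit <- data.table::data.table(
    gbatch = unique(obs[!(dataset %in% unscalable), gbatch]))
  fit[, dataset := sub("#[^#]*$", "", gbatch)]
  fit[, batch := as.integer(sub("^.*#", "", gbatch))]
  fit[, `:=`(k = 1, B = 0)]
  if (nrow(work) == 0 || length(ids) - length(unscalable) <= 1) {
    return(structure(list(batches = fit[], unscalable = unscalable,
                          n_iter = 0L, objective = NA_real_),
                     class = "scaling_model"))
  }
  work[, lnI := log(I)]
  obj_old <- Inf
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    work[fit, on = "gbatch", `:=`(k = i.k, B = i.B)]
    work[, resid0 := lnI - log(k) + 2 * B * s2]
    ref_tab <- work[, .(lnIh = mean(resid0)), by = key]
    work[ref_tab, on = "key", lnIh := i.lnIh]
    obj <- work[, sum((resid0 - lnIh)^2)]
    if (is.finite(obj_old) &&
        abs(obj_old - obj) <= tol * max(obj_old, 1e-12)) break
    obj_old <- obj
    if (n_iter >= max_iter) break
    ## per-batch (k, B) update; reference batches stay pinned
    upd <- work[dataset != reference_id,
                {
                  y <- lnI - lnIh
                  if (.N >= 3 && stats::sd(s2) > 0) {
                    cf <- stats::coef(stats::lm(y ~ s2))
                    list(k = exp(cf[1]), B = -cf[2] / 2)
                  } else {
                    list(k = exp(mean(y)), B = 0)
                  }
                }, by = gbatch]
    fit[upd, on = "gbatch", `:=`(k = i.k, B = i.B)]
  }
  structure(list(batches = fit[], unscalable = unscalable,
                 n_iter = n_iter, objective = obj),
            class = "scaling_model")
}

## Per-observation scale factor g = k exp(-2 B s^2) from a model.
apply_scaling <- function(obs, scaling) {
  obs <- data.table::copy(obs)
  obs[scaling$batches, on = "gbatch", `:=`(k = i.k, B = i.B)]
  obs <- obs[!is.na(k)]
  obs[, g := k * exp(-2 * B * s2)]
  obs[, `:=`(Isc = I / g, sigsc = sigma / g)]
  obs[]
}

#' Refine the per-dataset error model
#'
#' Fits (a, b) of the inflated variance model
#' sigma'^2 = a * (sigma_counting^2 + b * I^2) so that the normalised
#' deviations chi = (I - <I>_others) / sqrt(sigma'^2 + se_others^2)
#' have unit variance in ~10 equal-count intensity bins. a is bounded
#' to [0.25, 100] and b to [0, 0.25]; insufficient data returns (1, 0)
#' flagged.
#'
#' @param obs_scaled Scaled observations (from `apply_scaling`) of all
#'   datasets, with multiplicity >= 2 keys.
#' @param id Dataset whose model is refined.
#' @param n_bins Number of intensity bins.
#' @param min_obs Minimum usable observations (default 50).
#' @param models Optional named list of current error models for the
#'   other datasets; their corrected variances enter the denominator of
#'   chi (see [refine_error_models()]).
#' @return List with `a`, `b`, `ok` (FALSE when the fallback (1,0) was
#'   returned), `degenerate` (TRUE when a sits at its lower bound).
#' @export
refine_error_model <- function(obs_scaled, id, n_bins = 10, min_obs = 50,
                               models = NULL) {
  dt <- data.table::copy(obs_scaled)
  dt[, vmod := sigsc^2]
  if (!is.null(models)) {
    for (j in names(models)) {
      dt[dataset == j,
         vmod := models[[j]]$a * (sigsc^2 + models[[j]]$b * Isc^2)]
    }
  }
  dt[, m := .N, by = key]
  dt <- dt[m >= 2]
  dt[, `:=`(Ssum = sum(Isc), Vsum = sum(vmod)), by = key]
  mine <- dt[dataset == id]
  if (nrow(mine) < min_obs) {
    return(list(a = 1, b = 0, ok = FALSE, degenerate = FALSE))
  }
  mine[, loo := (Ssum - Isc) / (m - 1)]
  mine[, se2_others := (Vsum - vmod) / (m - 1)^2]
  mine[, delta := Isc - loo]
  ## gross corruption is excluded ONCE, judged by a fixed screening
  ## model with an intensity-proportional floor: the exclusion set must
  ## not move with (a, b) (or the optimizer is rewarded for pushing
  ## observations over the threshold), and legitimate proportional
  ## errors of a few percent of I must survive the screen
  mine[, dev0 := abs(delta) / sqrt(sigsc^2 + 0.01 * Isc^2 + se2_others)]
  mine <- mine[dev0 <= 10]
  if (nrow(mine) < min_obs) {
    return(list(a = 1, b = 0, ok = FALSE, degenerate = FALSE))
  }
  qs <- unique(stats::quantile(mine$Isc, probs = seq(0, 1, length.out = n_bins + 1)))
  mine[, bin := cut(Isc, qs, include.lowest = TRUE)]
  objective <- function(par) {
    a <- par[1]; b <- par[2]
    v <- a * (mine$sigsc^2 + b * mine$Isc^2) + mine$se2_others
    bv <- tapply(mine$delta^2 / v, mine$bin, mean)
    sum((bv - 1)^2, na.rm = TRUE)
  }
  res <- stats::optim(c(1, 0.001), objective, method = "L-BFGS-B",
                      lower = c(0.25, 0), upper = c(100, 0.25),
                      control = list(parscale = c(1, 0.01)))
  list(a = res$par[1], b = res$par[2], ok = TRUE,
       degenerate = res$par[1] <= 0.2500001)
}

#' Jointly refine error models for all datasets
#'
#' Two-round alternating refinement: the first round assumes plain
#' counting sigmas for everyone; the second recomputes each dataset's
#' chi denominators using the other datasets' round-one models. This
#' removes the upward bias in b that arises when the cohort's sigmas
#' are collectively understated.
#'
#' @param obs_scaled Scaled observations of the whole cohort.
#' @param ids Dataset ids to refine.
#' @param n_rounds Number of alternating rounds (default 2).
#' @return Named list of error models.
#' @export
refine_error_models <- function(obs_scaled, ids, n_rounds = 2) {
  models <- NULL
  for (r in seq_len(n_rounds)) {
    models <- stats::setNames(lapply(ids, function(id) {
      refine_error_model(obs_scaled, id, models = models)
    }), ids)
  }
  models
}

#' Merge scaled observations into unique reflections
#'
#' Inverse-variance weighted means of the scaled intensities, with a
#' single-pass robust rejection: an observation deviating more than
#' `reject_sd` times its corrected sigma from the weighted mean of the
#' other observations of the same reflection (only attempted at
#' multiplicity >= 3) is discarded. With `anomalous = TRUE` the
#' Friedel mates are additionally merged separately for the anomalous
#' statistics, while `Imean` pools both signs.
#'
#' @param obs_scaled Scaled observations (from `apply_scaling`).
#' @param error_models Named list (by dataset id) of error models from
#'   [refine_error_model()]; missing entries default to (1, 0).
#' @param anomalous Keep I+/I- separate for anomalous statistics?
#' @param reject_sd Rejection threshold in corrected sigmas.
#' @return A `merged_dataset`: list with `table` (key, hkl, d, Imean,
#'   sigma, mult), `anom` (per signed key), `observations` (the
#'   per-observation table with `kept` flags), `n_rejected`.
#' @export
merge_observations <- function(obs_scaled, error_models = list(),
                               anomalous = FALSE, reject_sd = 4) {
  dt <- data.table::copy(obs_scaled)
  dt[, `:=`(a_em = 1, b_em = 0)]
  for (id in names(error_models)) {
    em <- error_models[[id]]
    dt[dataset == id, `:=`(a_em = em$a, b_em = em$b)]
  }
  dt[, sigc := sqrt(a_em * (sigsc^2 + b_em * Isc^2))]
  dt[, w := 1 / sigc^2]
  ## single-pass leave-one-out rejection at multiplicity >= 3; at most
  ## a minority of a reflection's observations can be rejected (the
  ## worst deviators first), which prevents one gross outlier from
  ## masking the good observations into mutual rejection
  dt[, m := .N, by = key]
  dt[, `:=`(W = sum(w), Mw = sum(w * Isc)), by = key]
  dt[, loo := (Mw - w * Isc) / (W - w)]
  dt[, dev := abs(Isc - loo) / sigc]
  dt[, flagged := m >= 3 & dev > reject_sd]
  dt[, kept := {
    allowed <- (m[1] - 1) %/% 2
    k <- rep(TRUE, .N)
    idx <- which(flagged)
    if (length(idx) > 0 && allowed > 0) {
      k[idx[order(-dev[idx])][seq_len(min(length(idx), allowed))]] <- FALSE
    }
    k
  }, by = key]
  kept <- dt[kept == TRUE]
  merged <- kept[, .(Imean = sum(w * Isc) / sum(w),
                     sigma = 1 / sqrt(sum(w)),
                     mult = .N, d = d[1]), by = key]
  hkl <- asu_decode(merged$key)
  merged[, `:=`(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3])]
  anom <- NULL
  if (anomalous) {
    anom <- kept[, .(I = sum(w * Isc) / sum(w), sigma = 1 / sqrt(sum(w)),
                     mult = .N), by = .(key, sign)]
    anom <- data.table::dcast(anom, key ~ sign,
                              value.var = c("I", "sigma", "mult"))
    old <- c("I_1", "sigma_1", "mult_1", "I_-1", "sigma_-1", "mult_-1")
    new <- c("Iplus", "sigplus", "multplus", "Iminus", "sigminus", "multminus")
    for (j in seq_along(old)) {
      if (old[j] %in% names(anom)) data.table::setnames(anom, old[j], new[j])
      else anom[, (new[j]) := NA_real_]
    }
  }
  structure(list(table = merged[], anom = anom, observations = dt[],
                 n_rejected = sum(!dt$kept), anomalous = anomalous),
            class = "merged_dataset")
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat(sprintf("merged dataset: %d unique reflections, %d observations (%d rejected)\n",
              nrow(x$table), nrow(x$observations), x$n_rejected))
  invisible(x)
}

## Seeded per-reflection random half split of kept observations.
## Returns per (group key) the two half-set weighted means. Odd counts
## give the extra observation to half A.
half_set_means <- function(kept, by_col, seed) {
  dt <- data.table::copy(kept)
  data.table::setorderv(dt, c(by_col, "dataset", "frame"))
  with_seed(seed, {
    dt[, half := {
      n <- .N
      nA <- ceiling(n / 2)
      sample(c(rep("A", nA), rep("B", n - nA)))
    }, by = by_col]
  })
  hw <- dt[, .(Ih = sum(w * Isc) / sum(w), n = .N), by = c(by_col, "half")]
  data.table::dcast(hw, stats::as.formula(paste(paste(by_col, collapse = "+"),
                                                "~ half")),
                    value.var = "Ih")
}

cc_of_halves <- function(halves) {
  ok <- is.finite(halves$A) & is.finite(halves$B)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(halves$A[ok]) == 0 || stats::sd(halves$B[ok]) == 0) return(NA_real_)
  stats::cor(halves$A[ok], halves$B[ok])
}

#' Per-shell merging statistics
#'
#' Equal-volume resolution shells with, per shell and overall:
#' number of unique reflections, completeness against the
#' point-group-unique set, multiplicity, Rmeas (with the standard
#' sqrt(n/(n-1)) multiplicity correction), CC1/2 from a seeded random
#' half split of the observations, and CCano (correlation of the
#' anomalous differences I+ - I- between the two half-sets) when
#' anomalous. Friedel pairs count as distinct reflections for
#' multiplicity, CC1/2 and CCano in anomalous mode. Shells with fewer
#' than 3 unique reflections are flagged unreliable.
#'
#' @param merged A `merged_dataset` from [merge_observations()].
#' @param cell The (average) unit cell.
#' @param pg Merging [point_group()].
#' @param n_shells Number of shells (default 10).
#' @param seed Half-split seed.
#' @param d_min,d_max Resolution range; defaults to the observed range.
#' @return A `shell_stats` object: data.table with one row per shell
#'   plus an `overall` row.
#' @export
shell_statistics <- function(merged, cell, pg, n_shells = 10, seed = 1,
                             d_min = NULL, d_max = NULL) {
  kept <- merged$observations[kept == TRUE]
  anomalous <- isTRUE(merged$anomalous)
  if (is.null(d_min)) d_min <- min(kept$d)
  if (is.null(d_max)) d_max <- max(kept$d)
  kept <- kept[d >= d_min & d <= d_max]
  bounds <- shell_boundaries(d_max, d_min, n_shells)
  kept[, shell := shell_index(d, bounds)]
  ## counting key: Friedel mates separate in anomalous mode
  kept[, ckey := if (anomalous) key * 2 + (sign < 0) else key]

  uniq <- enumerate_unique(cell, pg, d_min, d_max, anomalous = anomalous)
  uniq[, shell := shell_index(d, bounds)]
  n_theory <- uniq[, .(n_theory = .N), by = shell]

  per_key <- kept[, .(m = .N, shell = shell[1],
                      wmean = sum(w * Isc) / sum(w),
                      absdev = sum(abs(Isc - sum(w * Isc) / sum(w))),
                      sumI = sum(Isc)), by = ckey]
  halves <- half_set_means(kept, "ckey", seed)
  halves[per_key, on = "ckey", shell := i.shell]

  calc_block <- function(pk, hv, n_th) {
    n_unique <- nrow(pk)
    n_obs <- sum(pk$m)
    multi <- pk[m >= 2]
    rmeas <- if (nrow(multi) > 0 && sum(abs(multi$sumI)) > 0) {
      sum(sqrt(multi$m / (multi$m - 1)) * multi$absdev) / sum(multi$sumI)
    } else NA_real_
    cc12 <- cc_of_halves(hv)
    list(n_unique = n_unique,
         completeness = 100 * n_unique / max(n_th, 1),
         multiplicity = n_obs / max(n_unique, 1),
         rmeas = rmeas, cc_half = cc12,
         reliable = n_unique >= 3)
  }
  rows <- list()
  for (sh in seq_len(n_shells)) {
    pk <- per_key[shell == sh]
    hv <- halves[shell == sh]
    nt <- n_theory[shell == sh, n_theory]
    if (length(nt) == 0) nt <- 0L
    b <- calc_block(pk, hv, nt)
    rows[[sh]] <- data.table::data.table(
      shell = sh, d_max = bounds[sh], d_min = bounds[sh + 1],
      n_unique = b$n_unique, completeness = b$completeness,
      multiplicity = b$multiplicity, rmeas = b$rmeas, cc_half = b$cc_half,
      cc_ano = NA_real_, reliable = b$reliable)
  }
  st <- data.table::rbindlist(rows)
  bo <- calc_block(per_key, halves, nrow(uniq))
  overall <- data.table::data.table(
    shell = NA_integer_, d_max = d_max, d_min = d_min,
    n_unique = bo$n_unique, completeness = bo$completeness,
    multiplicity = bo$multiplicity, rmeas = bo$rmeas, cc_half = bo$cc_half,
    cc_ano = NA_real_, reliable = bo$reliable)

  if (anomalous) {
    ## anomalous difference CC between half-sets: needs both signs of a
    ## reflection present in both halves
    ano <- data.table::copy(halves)
    ano[, `:=`(key = ckey %/% 2, neg = ckey %% 2)]
    wide <- data.table::dcast(ano, key ~ neg, value.var = c("A", "B"))
    if (all(c("A_0", "A_1", "B_0", "B_1") %in% names(wide))) {
      wide[, `:=`(dA = A_0 - A_1, dB = B_0 - B_1)]
      key_shell <- per_key[, .(key = ckey %/% 2, shell)][
        , .(shell = shell[1]), by = key]
      wide[key_shell, on = "key", shell := i.shell]
      ccano_of <- function(w) {
        ok <- is.finite(w$dA) & is.finite(w$dB)
        if (sum(ok) < 3) return(NA_real_)
        if (stats::sd(w$dA[ok]) == 0 || stats::sd(w$dB[ok]) == 0) return(NA_real_)
        stats::cor(w$dA[ok], w$dB[ok])
      }
      for (sh in seq_len(n_shells)) {
        st[shell == sh, cc_ano := ccano_of(wide[shell == sh])]
      }
      overall[, cc_ano := ccano_of(wide)]
    }
  }
  out <- data.table::rbindlist(list(st, overall))
  structure(out, class = c("shell_stats", class(out)))
}

#' Anisotropy analysis: CC1/2 along the reciprocal principal axes
#'
#' Every unique reflection is assigned to the reciprocal axis (a*, b*
#' or c*) whose direction maximises the absolute cosine with its
#' scattering vector, then CC1/2 is computed per axis in resolution
#' bins from a seeded half split; the per-axis summary is the
#' count-weighted mean CC1/2. Isotropic data give axes that agree;
#' anisotropic falloff along one axis depresses that axis's curve.
#' Axis bins with fewer than 3 unique reflections are flagged.
#'
#' @param merged A `merged_dataset`.
#' @param cell The unit cell.
#' @param n_bins Resolution bins per axis.
#' @param seed Half-split seed.
#' @return List with `curves` (data.table axis/bin/d/cc_half/n/flag)
#'   and `summary` (per-axis weighted mean CC1/2).
#' @export
anisotropy_cc <- function(merged, cell, n_bins = 5, seed = 1) {
  kept <- merged$observations[kept == TRUE]
  cell <- as_unit_cell(cell)
  ## Cartesian reciprocal basis
  ca <- cos(cell[4:6] * pi / 180); sg <- sin(cell[6] * pi / 180)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  L <- matrix(0, 3, 3)
  L[, 1] <- c(a, 0, 0)
  L[, 2] <- c(b * ca[3], b * sg, 0)
  cx <- cc * ca[2]
  cy <- cc * (ca[1] - ca[2] * ca[3]) / sg
  cz <- sqrt(max(cc^2 - cx^2 - cy^2, 0))
  L[, 3] <- c(cx, cy, cz)
  Astar <- t(solve(L))
  axes <- apply(Astar, 2, function(v) v / sqrt(sum(v^2)))

  hkl <- asu_decode(kept$key)
  xyz <- hkl %*% t(Astar)
  norms <- sqrt(rowSums(xyz^2))
  cosines <- abs(xyz %*% axes) / norms
  kept[, axis := c("a*", "b*", "c*")[max.col(cosines)]]

  d_min <- min(kept$d); d_max <- max(kept$d)
  bounds <- shell_boundaries(d_max, d_min, n_bins)
  kept[, bin := shell_index(d, bounds)]
  curves <- list()
  for (ax in c("a*", "b*", "c*")) {
    sub <- kept[axis == ax]
    for (bi in seq_len(n_bins)) {
      sb <- sub[bin == bi]
      n_uni <- length(unique(sb$key))
      cc12 <- if (n_uni >= 3) {
        cc_of_halves(half_set_means(sb, "key",
                                    child_seed(seed, bi * 7 + match(ax, c("a*", "b*", "c*")))))
      } else NA_real_
      curves[[length(curves) + 1]] <- data.table::data.table(
        axis = ax, bin = bi, d_max = bounds[bi], d_min = bounds[bi + 1],
        n_unique = n_uni, cc_half = cc12, flagged = n_uni < 3)
    }
  }
  curves <- data.table::rbindlist(curves)
  summary <- curves[!is.na(cc_half),
                    .(cc_half = sum(cc_half * n_unique) / sum(n_unique)),
                    by = axis]
  list(curves = curves, summary = summary)
}

#' Write a merged dataset as a tab-separated unique-reflection file
#'
#' Columns: h k l Imean sigma multiplicity, plus I+/sigI+/I-/sigI-
#' when anomalous.
#'
#' @param merged A `merged_dataset`.
#' @param path Output path.
#' @export
write_merged <- function(merged, path) {
  tab <- data.table::copy(merged$table)[order(-d)]
  out <- tab[, .(h, k, l, Imean = round(Imean, 4), sigma = round(sigma, 4),
                 multiplicity = mult)]
  if (!is.null(merged$anom)) {
    an <- merged$anom
    out <- merge(out, cbind(asu_decode(an$key),
                            an[, .(Iplus, sigplus, Iminus, sigminus)]),
                 by = c("h", "k", "l"), all.x = TRUE, sort = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
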