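## Ground-truth simulator: multi-wedge reflection cohorts with known
## intensities, indexing modes, cluster labels, scale/B factors,
## per-frame decay and injected outliers. Wedge geometry is emulated
## by random subsetting of the unique set (the pipeline uses nothing
## beyond frame numbers), radiation damage as linear-in-frame B
## inflation, and noise as sigma^2 = I + (c I)^2.

#' Generate ground-truth unique intensities
#'
#' Enumerates the asymmetric-unit reflections of a cell to `d_min` and
#' draws intensities from an acentric Wilson (exponential)
#' distribution scaled by exp(-2 B s^2). In anomalous mode, I+ and I-
#' are split by a zero-mean difference with mean |dI| / mean I equal
#' to `anomalous_fraction`.
#'
#' @param cell A [unit_cell()].
#' @param pg A [point_group()].
#' @param d_min High-resolution limit (Angstrom).
#' @param wilson_b Overall B factor (Angstrom^2, default 20).
#' @param anomalous_fraction Relative anomalous signal (default 0).
#' @param mean_intensity Mean intensity at zero scattering angle.
#' @param seed RNG seed.
#' @return A `ground_truth` object: list with `table` (key, h, k, l,
#'   d, I, Iplus, Iminus), `cell`, `pg`, `wilson_b`, `seed`.
#' @export
generate_truth <- function(cell, pg, d_min, wilson_b = 20,
                           anomalous_fraction = 0, mean_intensity = 1000,
                           seed = 1) {
  cell <- as_unit_cell(cell)
  uniq <- enumerate_unique(cell, pg, d_min)
  if (nrow(uniq) == 0) stop("empty unique reflection set")
  tab <- with_seed(seed, {
    I <- stats::rexp(nrow(uniq)) * mean_intensity *
      exp(-2 * wilson_b * s2_of_d(uniq$d))
    dI <- if (anomalous_fraction > 0) {
      stats::rnorm(nrow(uniq), 0, anomalous_fraction * mean(I) * sqrt(pi / 2))
    } else rep(0, nrow(uniq))
    hkl <- asu_decode(uniq$key)
    data.table::as.data.table(list(
      key = uniq$key, h = hkl[, 1], k = hkl[, 2], l = hkl[, 3], d = uniq$d,
      I = I, Iplus = pmax(I + dI / 2, 0.05 * I),
      Iminus = pmax(I - dI / 2, 0.05 * I)))
  })
  structure(list(table = tab, cell = cell, pg = pg, wilson_b = wilson_b,
                 anomalous_fraction = anomalous_fraction, seed = seed),
            class = "ground_truth")
}

default_outlier_spec <- function() {
  list(noisy = 0, nonisomorphous = 0, misindexed = 0, bad_frame_rate = 0)
}

#' Simulate a cohort of small-wedge datasets
#'
#' Per dataset: a random fraction of the unique set is observed,
#' spread uniformly over the wedge's frames; a cluster-specific truth
#' perturbation (intensity mixing with an alternative draw) and the
#' dataset's indexing mode, scale factor k, B factor and per-frame
#' decay are applied; then noise sigma^2 = I + (c I)^2. Outlier
#' classes: `noisy` (extra 15% intensity-proportional error),
#' `nonisomorphous` (intensities mixed
#' 70% with an independent truth), `misindexed` (cell lengths off by
#' 25%), and `bad_frame_rate` (fraction of frames whose observations
#' are replaced by uncorrelated values).
#'
#' @param truth A `ground_truth` from [generate_truth()].
#' @param n_datasets Number of wedges.
#' @param wedge_deg Wedge width in degrees.
#' @param deg_per_frame Oscillation per frame.
#' @param completeness_per_wedge Fraction of the unique set observed
#'   per wedge.
#' @param k_range,b_range Uniform sampling ranges for the true scale k
#'   and B factor.
#' @param decay_b_per_frame Radiation-damage B inflation per frame.
#' @param noise_c Fractional-error term of the noise model.
#' @param poisson Include the Poisson (counting) noise term? Setting
#'   `poisson = FALSE` with `noise_c = 0` yields exact observations.
#' @param sigma_model "honest" reports the full noise sigma;
#'   "counting" reports only the Poisson term, leaving the
#'   proportional component for the error model to recover.
#' @param ambiguity_ops Candidate indexing modes (list of operators);
#'   each dataset's recorded indices are its true mode applied to the
#'   true indices.
#' @param n_clusters Number of isomorphism classes.
#' @param cluster_perturbation Mixing weight p of the alternative
#'   truth for clusters beyond the first.
#' @param cluster_cell_shift Relative cell-length offset per extra
#'   cluster (for cell-based clustering scenarios).
#' @param cell_jitter_rel Per-dataset relative cell jitter.
#' @param anomalous Sample Friedel mates with their I+/I- truths?
#' @param outlier_spec See `default_outlier_spec()`; rates in [0, 1].
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @param out_dir Optional directory: writes one XDS_ASCII file per
#'   wedge plus `truth.json`.
#' @return List with `datasets` (list of [wedge_dataset()]),
#'   `truth_table` (per dataset: id, cluster, op_index, k, B, outlier
#'   class), `bad_frames` (data.table dataset/frame), `truth`.
#' @export
simulate_wedges <- function(truth, n_datasets = 30, wedge_deg = 5,
                            deg_per_frame = 0.5,
                            completeness_per_wedge = 0.2,
                            k_range = c(0.5, 2), b_range = c(0, 10),
                            decay_b_per_frame = 0, noise_c = 0.03,
                            ambiguity_ops = list(op_identity()),
                            n_clusters = 1, cluster_perturbation = 0,
                            cluster_cell_shift = 0, cell_jitter_rel = 0,
                            anomalous = FALSE, poisson = TRUE,
                            sigma_model = c("honest", "counting"),
                            outlier_spec = list(), seed = 1,
                            out_dir = NULL) {
  sigma_model <- match.arg(sigma_model)
  stopifnot(completeness_per_wedge > 0, completeness_per_wedge <= 1)
  spec <- utils::modifyList(default_outlier_spec(), outlier_spec)
  tt <- truth$table
  n_frames <- max(1L, as.integer(round(wedge_deg / deg_per_frame)))
  n_obs <- max(5L, round(completeness_per_wedge * nrow(tt)))

  res <- with_seed(seed, {
    ## per-cluster alternative truths for the isomorphism classes
    alt <- lapply(seq_len(max(n_clusters - 1, 0)) + 1, function(cl) {
      stats::rexp(nrow(tt)) * mean(tt$I) * exp(-2 * truth$wilson_b *
                                                 s2_of_d(tt$d)) /
        mean(exp(-2 * truth$wilson_b * s2_of_d(tt$d)))
    })
    iso_alt <- stats::rexp(nrow(tt)) *
      mean(tt$I) * exp(-2 * truth$wilson_b * s2_of_d(tt$d)) /
      mean(exp(-2 * truth$wilson_b * s2_of_d(tt$d)))

    n_out <- floor(c(noisy = spec$noisy, nonisomorphous = spec$nonisomorphous,
                     misindexed = spec$misindexed) * n_datasets)
    classes <- rep("none", n_datasets)
    pool <- seq_len(n_datasets)
    for (cl in names(n_out)) {
      if (n_out[[cl]] > 0) {
        pick <- pool[seq_len(n_out[[cl]])]
        classes[pick] <- cl
        pool <- setdiff(pool, pick)
      }
    }
    clusters <- rep_len(seq_len(n_clusters), n_datasets)
    op_idx <- sample.int(length(ambiguity_ops), n_datasets, replace = TRUE)
    ks <- stats::runif(n_datasets, k_range[1], k_range[2])
    Bs <- stats::runif(n_datasets, b_range[1], b_range[2])

    datasets <- vector("list", n_datasets)
    bad_frames <- list()
    for (i in seq_len(n_datasets)) {
      idx <- sample.int(nrow(tt), n_obs)
      frames <- sample.int(n_frames, n_obs, replace = TRUE)
      Itrue <- if (anomalous) {
        sgn <- sample(c(1L, -1L), n_obs, replace = TRUE)
        ifelse(sgn > 0, tt$Iplus[idx], tt$Iminus[idx])
      } else {
        sgn <- rep(1L, n_obs)
        tt$I[idx]
      }
      cl <- clusters[i]
      if (cl > 1 && cluster_perturbation > 0) {
        Itrue <- (1 - cluster_perturbation) * Itrue +
          cluster_perturbation * alt[[cl - 1]][idx]
      }
      if (classes[i] == "nonisomorphous") {
        Itrue <- 0.3 * Itrue + 0.7 * iso_alt[idx]
      }
      s2 <- s2_of_d(tt$d[idx])
      g <- ks[i] * exp(-2 * (Bs[i] + decay_b_per_frame * frames) * s2)
      Imod <- g * Itrue
      sig <- sqrt((if (poisson) pmax(Imod, 1) else 0) + (noise_c * Imod)^2)
      ## the noisy class carries a strong intensity-proportional error
      ## component (15%), the signature the b error-model parameter and
      ## its Tukey fence are meant to catch
      if (classes[i] == "noisy") sig <- sqrt(sig^2 + (0.15 * Imod)^2)
      Iobs <- Imod + (if (any(sig > 0)) stats::rnorm(n_obs, 0, sig) else 0)
      sig <- pmax(sig, 1e-4)  # reported sigma must stay positive
      ## "counting" mode reports only the Poisson part: the systematic
      ## component is left for the error model to discover
      if (sigma_model == "counting") sig <- sqrt(pmax(Imod, 1))
      ## bad frames: observations replaced by uncorrelated intensities
      n_bad <- round(spec$bad_frame_rate * n_frames)
      if (n_bad > 0) {
        ## incorrectly centred wedges go bad at the edges first
        bad <- unique(c(1L, n_frames, sample.int(n_frames, n_bad)))[seq_len(n_bad)]
        sel <- frames %in% bad
        Iobs[sel] <- stats::rexp(sum(sel)) * mean(pmax(Imod[sel], 1))
        bad_frames[[length(bad_frames) + 1]] <- data.table::data.table(
          dataset = sprintf("ds%03d", i), frame = bad)
      }
      ## recorded indices: true indexing mode applied to the true hkl
      hkl_true <- cbind(tt$h[idx], tt$k[idx], tt$l[idx]) *
        as.integer(sgn)
      hkl_rec <- hkl_true %*% t(ambiguity_ops[[op_idx[i]]])
      cell_i <- as.numeric(truth$cell)
      if (cl > 1 && cluster_cell_shift > 0) {
        cell_i[1:3] <- cell_i[1:3] * (1 + (cl - 1) * cluster_cell_shift)
      }
      if (cell_jitter_rel > 0) {
        cell_i[1:3] <- cell_i[1:3] *
          (1 + stats::rnorm(3, 0, cell_jitter_rel))
      }
      if (classes[i] == "misindexed") cell_i[1:3] <- cell_i[1:3] * 1.25
      refl <- data.table::data.table(
        h = hkl_rec[, 1], k = hkl_rec[, 2], l = hkl_rec[, 3],
        I = Iobs, sigma = sig, frame = frames)
      datasets[[i]] <- wedge_dataset(
        id = sprintf("ds%03d", i),
        cell = do.call(unit_cell, as.list(cell_i)),
        reflections = refl, space_group_number = 1L,
        wavelength = 1.0, frame_start = 1L, frame_end = n_frames,
        deg_per_frame = deg_per_frame)
    }
    list(datasets = datasets,
         truth_table = data.table::data.table(
           id = sprintf("ds%03d", seq_len(n_datasets)),
           cluster = clusters, op_index = op_idx, k = ks, B = Bs,
           outlier = classes),
         bad_frames = if (length(bad_frames)) {
           data.table::rbindlist(bad_frames)
         } else data.table::data.table(dataset = character(0),
                                       frame = integer(0)))
  })
  res$truth <- truth
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ds in res$datasets) {
      write_xds_ascii(ds, file.path(out_dir, paste0(ds$id, ".hkl")))
    }
    meta <- res$truth_table
    jsonlite::write_json(
      list(seed = seed, wilson_b = truth$wilson_b,
           cell = as.numeric(truth$cell), point_group = truth$pg$name,
           datasets = meta,
           bad_frames = res$bad_frames),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

## Right-coset label of an operator with respect to a point group and
## a list of coset representatives.
coset_index <- function(m, pg, reps) {
  pg_keys <- vapply(pg$ops, op_key, character(1))
  for (r in seq_along(reps)) {
    if (op_key(round(m %*% solve(reps[[r]]))) %in% pg_keys) return(r)
  }
  NA_integer_
}

#' Score pipeline outputs against the simulator's ground truth
#'
#' Computes: indexing-mode accuracy modulo a global operator (the
#' composed operator assigned-times-true must fall in one coset for
#' all datasets; accuracy is maximised over the global coset), cluster
#' adjusted Rand index, frame-rejection precision/recall, and the
#' correlation of merged with true intensities.
#'
#' @param sim Result of [simulate_wedges()].
#' @param assignment Optional `ambiguity_assignment`.
#' @param cluster_labels Optional named vector (dataset id ->
#'   cluster label) to score against the true clusters.
#' @param rejected_frames Optional data.table (dataset, frame).
#' @param merged Optional `merged_dataset`.
#' @return List of metrics (only those whose inputs were given).
#' @export
evaluate_against_truth <- function(sim, assignment = NULL,
                                   cluster_labels = NULL,
                                   rejected_frames = NULL, merged = NULL,
                                   global_ops = list(op_identity())) {
  out <- list()
  if (!is.null(assignment)) {
    ops <- assignment$ops
    pg <- sim$truth$pg
    composed <- lapply(seq_along(sim$datasets), function(i) {
      ops[[assignment$op_index[i]]] %*% ops[[sim$truth_table$op_index[i]]]
    })
    cosets <- vapply(composed, coset_index, integer(1), pg = pg, reps = ops)
    tab <- table(factor(cosets, levels = seq_along(ops)))
    out$op_accuracy <- max(tab) / length(cosets)
  }
  if (!is.null(cluster_labels)) {
    ids <- sim$truth_table$id
    got <- cluster_labels[ids]
    ok <- !is.na(got)
    out$cluster_ari <- adjusted_rand_index(got[ok],
                                           sim$truth_table$cluster[ok])
  }
  if (!is.null(rejected_frames)) {
    truthbf <- sim$bad_frames
    all_frames <- data.table::rbindlist(lapply(sim$datasets, function(ds) {
      data.table::data.table(dataset = ds$id,
                             frame = ds$frame_start:ds$frame_end)
    }))
    truth_key <- paste(truthbf$dataset, truthbf$frame)
    rej_key <- paste(rejected_frames$dataset, rejected_frames$frame)
    tp <- sum(rej_key %in% truth_key)
    out$frame_recall <- if (length(truth_key)) tp / length(truth_key) else NA
    out$frame_precision <- if (length(rej_key)) tp / length(rej_key) else NA
    neg <- nrow(all_frames) - length(truth_key)
    out$frame_fp_rate <- if (neg > 0) {
      sum(!(rej_key %in% truth_key)) / neg
    } else NA
  }
  if (!is.null(merged)) {
    out$cc_truth <- merged_truth_cc(merged, sim$truth, ops = global_ops)
  }
  out
}

#' Correlation of merged intensities with the ground truth
#'
#' Because an ambiguity-resolved cohort is only defined up to one
#' global reindexing operator, the correlation is maximised over the
#' supplied candidate global operators (default: identity only).
#'
#' @param merged A `merged_dataset`.
#' @param truth A `ground_truth`.
#' @param ops Candidate global operators (list of 3x3 matrices).
#' @return Pearson correlation over the shared unique reflections.
#' @export
merged_truth_cc <- function(merged, truth, ops = list(op_identity())) {
  best <- NA_real_
  for (op in ops) {
    hkl <- cbind(merged$table$h, merged$table$k, merged$table$l) %*% t(op)
    key2 <- map_to_asu(hkl, truth$pg)$key
    m <- merge(data.table::as.data.table(list(key = key2,
                                              Imean = merged$table$Imean)),
               truth$table[, .(key, I)], by = "key")
    if (nrow(m) < 3) next
    cc <- stats::cor(m$Imean, m$I)
    if (is.na(best) || cc > best) best <- cc
  }
  best
}
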