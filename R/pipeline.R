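## End-to-end drivers: per-cluster merging, automatic resolution
## cutoff from the CC1/2-versus-resolution curve, best-result
## selection and reporting.

#' Fit a sigmoid to the CC1/2-versus-resolution curve
#'
#' Least-squares fit of CC1/2(s) = c/2 * (1 - tanh((s - s0)/r)) with
#' s = 1/d, c in (0, 1], r > 0. On non-convergence a monotone linear
#' interpolation fallback is returned, flagged.
#'
#' @param d Shell resolutions (Angstrom; e.g. shell d_min midpoints).
#' @param cc_half Shell CC1/2 values (>= 4 finite values required).
#' @return List with `c`, `s0`, `r`, `predict(s)`, `residuals`,
#'   `fallback`.
#' @export
fit_cc_half_curve <- function(d, cc_half) {
  ok <- is.finite(d) & is.finite(cc_half)
  if (sum(ok) < 4) stop("need at least 4 shells with valid CC1/2")
  s <- 1 / d[ok]
  y <- cc_half[ok]
  c0 <- min(max(max(y), 0.1), 1)
  below <- which(y <= c0 / 2)
  s0_0 <- if (length(below) > 0) s[below[1]] else max(s) * 1.05
  r0 <- max((max(s) - min(s)) / 5, 1e-3)
  obj <- function(par) {
    cp <- par[1]; s0 <- par[2]; r <- par[3]
    sum((y - cp / 2 * (1 - tanh((s - s0) / r)))^2)
  }
  res <- tryCatch(
    stats::optim(c(c0, s0_0, r0), obj, method = "L-BFGS-B",
                 lower = c(1e-3, min(s) - 1, 1e-4),
                 upper = c(1, max(s) + 1, 10)),
    error = function(e) NULL)
  fallback <- is.null(res) || res$convergence != 0 ||
    ## pathological increasing curve: fit explains less than the mean
    stats::cor(s, y) > 0.5
  if (!fallback) {
    cp <- res$par[1]; s0 <- res$par[2]; r <- res$par[3]
    pred <- function(sq) cp / 2 * (1 - tanh((sq - s0) / r))
    return(list(c = cp, s0 = s0, r = r, predict = pred,
                residuals = y - pred(s), fallback = FALSE))
  }
  ## monotone fallback: linear interpolation on isotonic-decreasing y
  yd <- rev(stats::isoreg(rev(y))$yf)  # non-increasing in s
  pred <- stats::approxfun(s, yd, rule = 2)
  list(c = max(yd), s0 = NA_real_, r = NA_real_, predict = pred,
       residuals = y - pred(s), fallback = TRUE)
}

#' Estimate the high-resolution cutoff from a fitted CC1/2 curve
#'
#' The smallest d (highest resolution) at which the fitted CC1/2 is
#' still at or above `target`, clamped to the data edge. If an
#' `outer_cc_fn` is supplied, the cutoff is fine-tuned: the outer-shell
#' CC1/2 is recomputed at the candidate and the cutoff stepped one
#' shell at a time until the outer-shell value is within `tol` of the
#' target or the edge is reached.
#'
#' @param fit Result of [fit_cc_half_curve()].
#' @param d_edge Highest resolution present in the data (Angstrom).
#' @param d_low Lowest resolution (for the search range).
#' @param target CC1/2 target (default 0.5).
#' @param outer_cc_fn Optional function(d_cutoff) -> outer-shell CC1/2.
#' @param shell_step Step width in d (Angstrom) for fine-tuning.
#' @param tol Fine-tune tolerance around the target (default 0.15).
#' @return The cutoff d in Angstrom (>= d_edge).
#' @export
estimate_cutoff <- function(fit, d_edge, d_low, target = 0.5,
                            outer_cc_fn = NULL, shell_step = NULL,
                            tol = 0.15, max_steps = 6) {
  if (target <= 0) return(d_edge)
  s_grid <- seq(1 / d_low, 1 / d_edge, length.out = 400)
  cc_grid <- fit$predict(s_grid)
  above <- cc_grid >= target
  if (all(above)) {
    d_cut <- d_edge
  } else if (!above[1]) {
    d_cut <- d_low
  } else {
    s_cross <- s_grid[max(which(above))]
    d_cut <- max(1 / s_cross, d_edge)
  }
  if (!is.null(outer_cc_fn) && d_cut > d_edge) {
    if (is.null(shell_step)) shell_step <- (d_low - d_edge) / 20
    for (step in seq_len(max_steps)) {
      occ <- outer_cc_fn(d_cut)
      if (!is.finite(occ) || abs(occ - target) <= tol) break
      d_new <- if (occ < target) d_cut + shell_step else d_cut - shell_step
      d_new <- max(d_new, d_edge)
      if (abs(d_new - d_cut) < 1e-9) break
      d_cut <- d_new
    }
  }
  d_cut
}

overall_cc <- function(stats) stats[is.na(shell), cc_half]
outer_cc <- function(stats) {
  sh <- stats[!is.na(shell)]
  sh[which.max(sh$shell), cc_half]
}

default_multi_merge_options <- function() {
  c(default_merge_config(),
    list(clustering = "cc", cc_metric = "one_minus_cc", cc_values = "raw",
         completeness_min = 0.9, multiplicity_min = 2,
         prefilter_tol_len = 0.1, prefilter_tol_ang = 3,
         max_clusters = 10L))
}

#' Cluster a cohort and merge every candidate cluster
#'
#' Prefilters extreme cells, clusters the datasets (by intensity CC,
#' by unit cell, or not at all), selects the clusters exceeding the
#' completeness/multiplicity thresholds, and runs the full
#' scale-merge-reject cycle on each. Runs are sorted by overall CC1/2
#' with outer-shell CC1/2 as tie-break.
#'
#' @param datasets Consistently indexed [wedge_dataset()]s.
#' @param pg Merging [point_group()].
#' @param options See `default_multi_merge_options()`; `clustering`
#'   is "cc", "cell" or "none".
#' @return List with `runs` (list of merge runs: members, stats,
#'   cc_overall, cc_outer, lcv, log, merged), `tree`, `prefilter`,
#'   `excluded`.
#' @export
multi_merge <- function(datasets, pg, options = list()) {
  options <- utils::modifyList(default_multi_merge_options(), options)
  pf <- prefilter_cells(datasets, options$prefilter_tol_len,
                        options$prefilter_tol_ang)
  datasets <- pf$kept
  if (length(datasets) < 2) stop("fewer than 2 datasets after cell prefilter")
  ids <- vapply(datasets, function(d) d$id, character(1))
  tree <- NULL
  excluded <- NULL
  if (options$clustering == "none") {
    candidates <- data.table::data.table(
      node = NA_integer_, n_members = length(datasets),
      lcv = lcv_percent(lapply(datasets, function(d) d$cell)),
      members = list(ids))
  } else {
    if (options$clustering == "cc") {
      dmat <- cc_distance_matrix(datasets, pg, metric = options$cc_metric,
                                 values = options$cc_values,
                                 min_common = options$min_common)
      excluded <- dmat$excluded
      tree <- hierarchical_cluster(dmat, datasets)
    } else {
      tree <- cell_cluster(datasets)
    }
    candidates <- select_cluster_candidates(
      tree, datasets, pg, d_min = options$d_min,
      completeness_min = options$completeness_min,
      multiplicity_min = options$multiplicity_min,
      anomalous = options$anomalous)
    if (nrow(candidates) == 0) {
      stop("no cluster exceeds the thresholds; lower completeness_min or ",
           "multiplicity_min")
    }
    candidates <- utils::head(candidates, options$max_clusters)
  }
  runs <- list()
  for (i in seq_len(nrow(candidates))) {
    members <- candidates$members[[i]]
    dss <- datasets[match(members, ids)]
    run <- tryCatch(
      run_rejection_cycles(dss, pg, options),
      error = function(e) NULL)
    if (is.null(run)) next
    runs[[length(runs) + 1]] <- list(
      cluster_node = candidates$node[i],
      members = members, n_datasets = length(run$datasets),
      lcv = candidates$lcv[i],
      stats = run$stats,
      cc_overall = overall_cc(run$stats),
      cc_outer = outer_cc(run$stats),
      d_cutoff = run$stats[is.na(shell), d_min],
      log = run$log, merged = run$merged)
  }
  if (length(runs) == 0) stop("every candidate cluster failed to merge")
  ord <- order(-vapply(runs, function(r) r$cc_overall, numeric(1)),
               -vapply(runs, function(r) r$cc_outer, numeric(1)))
  list(runs = runs[ord], tree = tree, prefilter = pf$rejected,
       excluded = excluded)
}

#' Read a sample sheet
#'
#' CSV with columns `root_dir`, `name`, `anomalous`, `reference`
#' (reference may be empty).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE,
                           strip.white = TRUE)
  need <- c("root_dir", "name", "anomalous")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns root_dir, name, anomalous")
  }
  if (!("reference" %in% names(sheet))) sheet$reference <- ""
  if (anyDuplicated(sheet$name)) stop("sample names must be unique")
  sheet$anomalous <- as.logical(sheet$anomalous)
  sheet
}

#' Fully automated multi-sample merging
#'
#' Per sample: discover datasets, group by lattice, tally symmetry
#' candidates, resolve the indexing ambiguity (against the reference
#' file when given, else by selective breeding), merge at the data
#' edge, estimate the CC1/2 = 0.5 resolution cutoff from the best
#' run's shell curve, merge once more at that cutoff, and keep the run
#' with the highest overall CC1/2 (outer-shell CC1/2 as tie-break).
#' Per-sample failures are isolated and reported.
#'
#' @param sheet A data.frame from [read_sample_sheet()] (or of the
#'   same shape).
#' @param options Options for [multi_merge()] plus `sym_tol`
#'   (ambiguity-operator tolerance, default 0.02), `vote_tol`
#'   (per-dataset symmetry vote tolerance, default 0.005),
#'   `cc_target` (default 0.5).
#' @return Named list per sample: `best` run, `runs_pass1`,
#'   `runs_pass2`, `d_cutoff`, `groups`, `assignment`, or `error`.
#' @export
auto_multi_merge <- function(sheet, options = list()) {
  if (nrow(sheet) == 0) stop("empty sample sheet")
  defaults <- c(default_multi_merge_options(),
                list(sym_tol = 0.02, vote_tol = 0.005, cc_target = 0.5))
  options <- utils::modifyList(defaults, options)
  out <- list()
  for (i in seq_len(nrow(sheet))) {
    name <- sheet$name[i]
    out[[name]] <- tryCatch({
      datasets <- discover_datasets(sheet$root_dir[i])
      if (length(datasets) < 2) stop("sample ", name, ": < 2 datasets")
      groups <- build_lattice_groups(datasets, sym_tol = options$vote_tol)
      if (length(groups$groups) == 0) stop("no lattice group of size >= 2")
      grp <- groups$groups[[1]]
      ids <- vapply(datasets, function(d) d$id, character(1))
      datasets <- datasets[match(grp$member_ids, ids)]
      pg <- point_group(grp$symmetry_candidates$label[1])
      ops <- ambiguity_operators(grp$averaged_cell, pg, options$sym_tol)
      assignment <- NULL
      if (length(ops) > 1) {
        reffile <- sheet$reference[i]
        assignment <- if (!is.na(reffile) && nzchar(reffile)) {
          resolve_by_reference(datasets, ops, read_xds_ascii(reffile), pg,
                               min_common = options$min_common)
        } else {
          resolve_selective_breeding(datasets, ops, pg,
                                     seed = options$seed,
                                     min_common = options$min_common)
        }
        datasets <- apply_assignment(datasets, assignment)
      }
      opts1 <- options
      opts1$anomalous <- isTRUE(sheet$anomalous[i])
      pass1 <- multi_merge(datasets, pg, opts1)
      best1 <- pass1$runs[[1]]
      sh <- best1$stats[!is.na(shell) & reliable == TRUE]
      d_cut <- tryCatch({
        fit <- fit_cc_half_curve(sh$d_min, sh$cc_half)
        estimate_cutoff(fit, d_edge = min(sh$d_min), d_low = max(sh$d_max),
                        target = options$cc_target)
      }, error = function(e) min(sh$d_min))
      opts2 <- opts1
      opts2$d_min <- d_cut
      pass2 <- multi_merge(datasets, pg, opts2)
      best <- pass2$runs[[1]]
      list(best = best, runs_pass1 = pass1$runs, runs_pass2 = pass2$runs,
           d_cutoff = d_cut, groups = groups, assignment = assignment,
           point_group = pg$name)
    }, error = function(e) list(error = conditionMessage(e)))
  }
  out
}

run_row <- function(run) {
  sh <- run$stats[!is.na(shell)]
  inner <- sh[which.min(sh$shell)]
  list(cluster_node = if (is.na(run$cluster_node)) "all" else
         as.character(run$cluster_node),
       n_datasets = run$n_datasets,
       lcv_percent = round(run$lcv, 3),
       multiplicity = round(run$stats[is.na(shell), multiplicity], 3),
       completeness = round(run$stats[is.na(shell), completeness], 2),
       rmeas = round(run$stats[is.na(shell), rmeas], 4),
       cc_half_overall = round(run$cc_overall, 4),
       cc_half_inner = round(inner$cc_half, 4),
       cc_half_outer = round(run$cc_outer, 4),
       d_cutoff = round(run$d_cutoff, 3))
}

#' Write machine- and human-readable merge reports
#'
#' `report.json` carries every run's summary row and per-shell
#' statistics; `report.html` is a static table (one row per cluster:
#' LCV, dataset count, multiplicity, inner/outer CC1/2).
#'
#' @param runs List of merge runs (from [multi_merge()]).
#' @param out_dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
render_report <- function(runs, out_dir) {
  stopifnot(length(runs) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(runs, run_row)
  payload <- list(
    n_runs = length(runs),
    runs = lapply(seq_along(runs), function(i) {
      st <- data.table::copy(runs[[i]]$stats)
      st[, shell := as.integer(shell)]
      c(rows[[i]], list(members = runs[[i]]$members,
                        shells = st))
    }))
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
  cols <- c("cluster", "LCV (%)", "n datasets", "multiplicity",
            "completeness (%)", "CC1/2 inner", "CC1/2 outer",
            "CC1/2 overall", "d cutoff (A)")
  html_rows <- vapply(rows, function(r) {
    paste0("<tr><td>", paste(c(r$cluster_node, r$lcv_percent, r$n_datasets,
                               r$multiplicity, r$completeness,
                               r$cc_half_inner, r$cc_half_outer,
                               r$cc_half_overall, r$d_cutoff),
                             collapse = "</td><td>"), "</td></tr>")
  }, character(1))
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>merging report</title></head><body>",
            "<h1>Cluster merging results</h1>",
            "<table border='1'><tr><th>",
            paste(cols, collapse = "</th><th>"), "</th></tr>",
            html_rows, "</table></body></html>")
  html_path <- file.path(out_dir, "report.html")
  writeLines(html, html_path)
  invisible(c(json = json_path, html = html_path))
}
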