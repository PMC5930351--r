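## Resolving the indexing ambiguity: assign each wedge one reindexing
## operator so that all wedges share a single indexing convention.

## Per-dataset unique intensities after applying a reindexing operator
## and mapping to the asymmetric unit. Duplicate observations of the
## same unique reflection are pre-averaged (unweighted).
unique_intensities <- function(dataset, op, pg) {
  r <- dataset$reflections
  hkl <- cbind(r$h, r$k, r$l) %*% t(op)
  key <- map_to_asu(hkl, pg)$key
  dt <- data.table::as.data.table(list(key = key, I = r$I))
  dt[, .(I = mean(I)), by = key]
}

## Dense matrix of unique intensities, one column per (dataset, op)
## variant, rows = union of unique-reflection keys; NA where absent.
## cor(..., use = "pairwise") on this matrix gives every pairwise CC in
## one call.
variant_matrix <- function(datasets, ops, pg) {
  tabs <- list()
  for (i in seq_along(datasets)) {
    for (p in seq_along(ops)) {
      tabs[[length(tabs) + 1]] <- unique_intensities(datasets[[i]], ops[[p]], pg)
    }
  }
  keys <- sort(unique(unlist(lapply(tabs, `[[`, "key"))))
  M <- matrix(NA_real_, length(keys), length(tabs))
  for (j in seq_along(tabs)) {
    M[match(tabs[[j]]$key, keys), j] <- tabs[[j]]$I
  }
  list(M = M, keys = keys, n_datasets = length(datasets), n_ops = length(ops))
}

#' Pairwise intensity correlation between two wedges
#'
#' Pearson correlation over the unique reflections the two datasets
#' have in common, after applying the given reindexing operators and
#' mapping to the asymmetric unit of the merging point group.
#' Duplicate observations within a dataset are pre-averaged.
#'
#' @param ds_i,ds_j [wedge_dataset()]s.
#' @param pg Merging [point_group()].
#' @param op_i,op_j Reindexing operators (default identity).
#' @param min_common Minimum number of common unique reflections for
#'   the CC to count as defined.
#' @return List with `cc` (NA when the overlap is insufficient),
#'   `n_common` and `sufficient`.
#' @export
pairwise_cc <- function(ds_i, ds_j, pg, op_i = op_identity(),
                        op_j = op_identity(), min_common = 3) {
  ti <- unique_intensities(ds_i, op_i, pg)
  tj <- unique_intensities(ds_j, op_j, pg)
  m <- merge(ti, tj, by = "key")
  n <- nrow(m)
  if (n < min_common || stats::sd(m$I.x) == 0 || stats::sd(m$I.y) == 0) {
    return(list(cc = NA_real_, n_common = n, sufficient = FALSE))
  }
  list(cc = stats::cor(m$I.x, m$I.y), n_common = n, sufficient = TRUE)
}

## CC matrix between all (dataset, op) variants, entries with
## insufficient overlap set NA. Column index of variant (i, p) is
## (i-1)*n_ops + p.
variant_cc <- function(vm, min_common) {
  suppressWarnings({
    CC <- stats::cor(vm$M, use = "pairwise.complete.obs")
  })
  NC <- crossprod(!is.na(vm$M))
  CC[NC < min_common] <- NA_real_
  diag(CC) <- NA_real_
  CC
}

vcol <- function(i, p, n_ops) (i - 1L) * n_ops + p

## Sum of CC between dataset i under op p and all other datasets under
## their current assignment; NAs contribute 0.
assignment_score <- function(CC, assign, i, p, n_ops) {
  cols <- vcol(seq_along(assign), assign, n_ops)
  v <- CC[vcol(i, p, n_ops), cols[-i]]
  sum(v, na.rm = TRUE)
}

total_objective <- function(CC, assign, n_ops) {
  cols <- vcol(seq_along(assign), assign, n_ops)
  sub <- CC[cols, cols]
  sum(sub[upper.tri(sub)], na.rm = TRUE)
}

breeding_ascent <- function(CC, n, n_ops, start, max_cycles) {
  assign <- start
  n_cycles <- 0L
  trace <- total_objective(CC, assign, n_ops)
  repeat {
    n_cycles <- n_cycles + 1L
    changed <- FALSE
    for (i in seq_len(n)) {
      scores <- vapply(seq_len(n_ops), function(p) {
        assignment_score(CC, assign, i, p, n_ops)
      }, numeric(1))
      best <- which(scores > scores[assign[i]] + 1e-12)
      if (length(best) > 0) {
        ## strict improvement only; ties broken toward lower op index
        assign[i] <- which.max(round(scores, 12))
        changed <- TRUE
      }
    }
    trace <- c(trace, total_objective(CC, assign, n_ops))
    if (!changed || n_cycles >= max_cycles) break
  }
  list(assign = assign, n_cycles = n_cycles,
       objective = trace[length(trace)], objective_trace = trace)
}

#' Resolve indexing ambiguity against reference data
#'
#' Each dataset is assigned the candidate operator that maximises its
#' intensity correlation with the reference (an already consistently
#' indexed dataset, e.g. a merged isomorphous dataset or one of the
#' wedges).
#'
#' @param datasets List of [wedge_dataset()]s.
#' @param ops Candidate operators from [ambiguity_operators()].
#' @param reference A [wedge_dataset()] or a data.frame with columns
#'   `key` and `I` (asymmetric-unit keys as from [map_to_asu()]).
#' @param pg Merging [point_group()].
#' @param min_common Minimum overlap for a defined CC.
#' @return An `ambiguity_assignment`: list with `op_index` (per
#'   dataset), `mean_cc`, `unresolved` (logical), `n_cycles = 1`.
#' @export
resolve_by_reference <- function(datasets, ops, reference, pg,
                                 min_common = 3) {
  ref <- if (inherits(reference, "wedge_dataset")) {
    unique_intensities(reference, op_identity(), pg)
  } else {
    data.table::as.data.table(reference)[, .(I = mean(I)), by = key]
  }
  n <- length(datasets)
  op_index <- integer(n)
  mean_cc <- rep(NA_real_, n)
  unresolved <- logical(n)
  for (i in seq_len(n)) {
    ccs <- rep(NA_real_, length(ops))
    nn <- integer(length(ops))
    for (p in seq_along(ops)) {
      t <- unique_intensities(datasets[[i]], ops[[p]], pg)
      m <- merge(t, ref, by = "key")
      nn[p] <- nrow(m)
      if (nrow(m) >= min_common && stats::sd(m$I.x) > 0 &&
          stats::sd(m$I.y) > 0) {
        ccs[p] <- stats::cor(m$I.x, m$I.y)
      }
    }
    if (all(is.na(ccs))) {
      op_index[i] <- 1L
      unresolved[i] <- TRUE
    } else {
      op_index[i] <- which.max(round(ccs, 12))
      mean_cc[i] <- ccs[op_index[i]]
    }
  }
  if (all(unresolved)) {
    stop("reference shares fewer than ", min_common,
         " reflections with every dataset")
  }
  structure(list(op_index = op_index, mean_cc = mean_cc,
                 unresolved = unresolved, n_cycles = 1L,
                 ops = ops, method = "reference"),
            class = "ambiguity_assignment")
}

#' Resolve indexing ambiguity by iterative correlation ascent
#'
#' A selective-breeding style resolver: starting from an initial
#' assignment, each dataset in turn is reassigned the operator that
#' maximises its summed intensity correlation with all other datasets
#' under their current operators; cycles repeat until no assignment
#' changes. The total pairwise-CC objective is non-decreasing across
#' cycles. Several restarts (all-identity plus seeded random starts)
#' guard against poor local optima; the best objective wins. The
#' solution is only defined up to one global operator applied to every
#' dataset.
#'
#' @param datasets List of [wedge_dataset()]s (>= 2).
#' @param ops Candidate operators (>= 2).
#' @param pg Merging [point_group()].
#' @param seed Integer seed controlling the random restarts.
#' @param max_cycles Cycle cap per restart.
#' @param n_restarts Number of starts (first is all-identity).
#' @param min_common Minimum overlap for a defined pairwise CC.
#' @return An `ambiguity_assignment` (see [resolve_by_reference()]);
#'   `mean_cc` holds each dataset's mean CC against all others at
#'   convergence and `objectives` the per-cycle objective trace of the
#'   winning restart.
#' @export
resolve_selective_breeding <- function(datasets, ops, pg, seed = 1,
                                       max_cycles = 20, n_restarts = 4,
                                       min_common = 3) {
  n <- length(datasets)
  n_ops <- length(ops)
  stopifnot(n >= 2, n_ops >= 2)
  vm <- variant_matrix(datasets, ops, pg)
  CC <- variant_cc(vm, min_common)
  ## connectivity: every dataset needs a defined CC with some other
  for (i in seq_len(n)) {
    mine <- vcol(i, seq_len(n_ops), n_ops)
    others <- setdiff(seq_len(n * n_ops), vcol(i, seq_len(n_ops), n_ops))
    if (all(is.na(CC[mine, others]))) {
      stop("dataset ", datasets[[i]]$id, " shares fewer than ", min_common,
           " reflections with every other dataset")
    }
  }
  starts <- c(list(rep(1L, n)), with_seed(seed, {
    lapply(seq_len(max(0, n_restarts - 1)), function(r) {
      sample.int(n_ops, n, replace = TRUE)
    })
  }))
  best <- NULL
  for (st in starts) {
    res <- breeding_ascent(CC, n, n_ops, st, max_cycles)
    if (is.null(best) || res$objective > best$objective + 1e-12) best <- res
  }
  assign <- best$assign
  cols <- vcol(seq_len(n), assign, n_ops)
  sub <- CC[cols, cols]
  mean_cc <- rowMeans(sub, na.rm = TRUE)
  structure(list(op_index = assign, mean_cc = mean_cc,
                 unresolved = rep(FALSE, n), n_cycles = best$n_cycles,
                 objective = best$objective,
                 objective_trace = best$objective_trace, ops = ops,
                 method = "breeding"),
            class = "ambiguity_assignment")
}

#' Apply a resolved assignment to datasets
#'
#' Rewrites each dataset's Miller indices through its assigned
#' operator so that all datasets share one indexing convention.
#'
#' @param datasets List of [wedge_dataset()]s.
#' @param assignment An `ambiguity_assignment`.
#' @return List of reindexed datasets.
#' @export
apply_assignment <- function(datasets, assignment) {
  mapply(function(ds, pi) {
    op <- assignment$ops[[pi]]
    r <- data.table::copy(ds$reflections)
    hkl <- cbind(r$h, r$k, r$l) %*% t(op)
    r[, `:=`(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
             l = as.integer(hkl[, 3]))]
    ds$reflections <- r
    ds
  }, datasets, assignment$op_index, SIMPLIFY = FALSE)
}
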