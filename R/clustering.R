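## Hierarchical clustering of datasets by intensity correlation or by
## unit-cell variation, and selection of merge-worthy clusters.

#' Estimate an overall Wilson B factor
#'
#' Least-squares slope of ln(mean intensity) versus s^2
#' (s = sin(theta)/lambda = 1/(2d)) over the high-resolution fit
#' region: d < 4 Angstrom when the data extend beyond 4 Angstrom,
#' otherwise the higher-resolution half of the s^2 range. B is minus
#' half the slope.
#'
#' @param dataset A [wedge_dataset()].
#' @param n_bins Number of equal-count resolution bins for the fit.
#' @return List with `wilson_b` (NA when the fit region is too thin)
#'   and `ok`.
#' @export
estimate_wilson_b <- function(dataset, n_bins = 10) {
  r <- dataset$reflections
  if (nrow(r) < 20) return(list(wilson_b = NA_real_, ok = FALSE))
  d <- d_spacing(cbind(r$h, r$k, r$l), dataset$cell)
  s2 <- s2_of_d(d)
  if (min(d) < 4) {
    sel <- d < 4
  } else {
    sel <- s2 > (min(s2) + max(s2)) / 2
  }
  s2 <- s2[sel]; I <- r$I[sel]
  if (length(I) < 20) return(list(wilson_b = NA_real_, ok = FALSE))
  qs <- stats::quantile(s2, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(s2, unique(qs), include.lowest = TRUE)
  mI <- tapply(I, bin, mean)
  ms2 <- tapply(s2, bin, mean)
  keep <- is.finite(mI) & mI > 0
  if (sum(keep) < 2) return(list(wilson_b = NA_real_, ok = FALSE))
  fit <- stats::lm(log(mI[keep]) ~ ms2[keep])
  list(wilson_b = -unname(stats::coef(fit)[2]) / 2, ok = TRUE)
}

## |E|^2-style normalization: intensity divided by its per-dataset
## resolution-shell mean. The per-shell mean of the normalized values
## is 1 by construction.
normalize_e2 <- function(I, d, n_bins = 10) {
  s2 <- s2_of_d(d)
  qs <- unique(stats::quantile(s2, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(s2, qs, include.lowest = TRUE)
  mI <- tapply(I, bin, mean)
  mI[!is.finite(mI) | mI <= 0] <- NA
  I / mI[bin]
}

#' Pairwise CC-based distance matrix between datasets
#'
#' Distances d = sqrt(1 - CC) (default) or sqrt(1 - CC^2), with CC the
#' Pearson correlation over common unique reflections. Intensities can
#' be used raw, corrected toward a common Wilson B
#' (`wilson_scaled`), or replaced by squared normalized amplitudes
#' (`e2`). Datasets sharing fewer than `min_common` reflections with
#' every other dataset are excluded (with reasons); an undefined CC
#' between two retained datasets is assigned the maximal distance.
#'
#' @param datasets List of consistently indexed [wedge_dataset()]s.
#' @param pg Merging [point_group()].
#' @param metric "one_minus_cc" or "one_minus_cc_sq".
#' @param values "raw", "wilson_scaled" or "e2".
#' @param min_common Minimum common reflections (default 3).
#' @return List with `dist` (matrix, dimnames = dataset ids), `cc`
#'   (CC matrix), `n_common`, `ids`, `excluded` (data.frame id/reason).
#' @export
cc_distance_matrix <- function(datasets, pg,
                               metric = c("one_minus_cc", "one_minus_cc_sq"),
                               values = c("raw", "wilson_scaled", "e2"),
                               min_common = 3) {
  metric <- match.arg(metric)
  values <- match.arg(values)
  n <- length(datasets)
  ids <- vapply(datasets, function(d) d$id, character(1))
  tabs <- vector("list", n)
  bs <- rep(NA_real_, n)
  if (values == "wilson_scaled") {
    bs <- vapply(datasets, function(d) estimate_wilson_b(d)$wilson_b,
                 numeric(1))
    b_ref <- stats::median(bs, na.rm = TRUE)
  }
  for (i in seq_len(n)) {
    r <- datasets[[i]]$reflections
    hkl <- cbind(r$h, r$k, r$l)
    key <- map_to_asu(hkl, pg)$key
    d <- d_spacing(hkl, datasets[[i]]$cell)
    I <- r$I
    if (values == "wilson_scaled" && is.finite(bs[i])) {
      I <- I * exp(2 * (bs[i] - b_ref) * s2_of_d(d))
    } else if (values == "e2") {
      I <- normalize_e2(I, d)
    }
    dt <- data.table::as.data.table(list(key = key, I = I))
    tabs[[i]] <- dt[is.finite(I), .(I = mean(I)), by = key]
  }
  keys <- sort(unique(unlist(lapply(tabs, `[[`, "key"))))
  M <- matrix(NA_real_, length(keys), n)
  for (j in seq_len(n)) M[match(tabs[[j]]$key, keys), j] <- tabs[[j]]$I
  NC <- crossprod(!is.na(M))
  suppressWarnings(CC <- stats::cor(M, use = "pairwise.complete.obs"))
  CC[NC < min_common] <- NA_real_
  diag(CC) <- 1
  diag(NC) <- 0
  isolated <- vapply(seq_len(n), function(i) {
    all(is.na(CC[i, -i])) || all(NC[i, -i] < min_common)
  }, logical(1))
  excluded <- data.frame(
    id = ids[isolated],
    reason = rep(sprintf(
      "fewer than %d reflections in common with any other dataset",
      min_common), sum(isolated)),
    stringsAsFactors = FALSE)
  keep <- which(!isolated)
  if (length(keep) < 2) {
    stop("fewer than 2 datasets remain after the min_common filter")
  }
  CC <- CC[keep, keep, drop = FALSE]
  D <- if (metric == "one_minus_cc") {
    sqrt(pmax(1 - CC, 0))
  } else {
    sqrt(pmax(1 - CC^2, 0))
  }
  D[is.na(D)] <- sqrt(2)
  diag(D) <- 0
  dimnames(D) <- list(ids[keep], ids[keep])
  list(dist = D, cc = CC, n_common = NC[keep, keep, drop = FALSE],
       ids = ids[keep], excluded = excluded, metric = metric, values = values)
}

## Face diagonals of a cell (law of cosines on each face); the basis
## of the linear-cell-variation statistic.
cell_face_diagonals <- function(cell) {
  cell <- as_unit_cell(cell)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  c(ab = sqrt(a^2 + b^2 - 2 * a * b * cos(ga)),
    bc = sqrt(b^2 + cc^2 - 2 * b * cc * cos(al)),
    ac = sqrt(a^2 + cc^2 - 2 * a * cc * cos(be)))
}

#' Linear cell variation of a set of cells
#'
#' Maximum over the three cell-face diagonals of the relative spread
#' (max - min)/min across the cells, in percent. Zero for identical
#' cells; a large value flags non-isomorphism within a cluster.
#'
#' @param cells List of [unit_cell()]s.
#' @return LCV in percent.
#' @export
lcv_percent <- function(cells) {
  if (length(cells) < 2) return(0)
  diags <- vapply(cells, cell_face_diagonals, numeric(3))
  spread <- apply(diags, 1, function(v) (max(v) - min(v)) / min(v))
  100 * max(spread)
}

## Annotate an hclust tree: per internal node its members, height, LCV.
build_cluster_tree <- function(hc, ids, cells = NULL) {
  n <- length(ids)
  members <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    pick <- function(x) if (x < 0) -x else NULL
    left <- hc$merge[m, 1]; right <- hc$merge[m, 2]
    mem <- c(if (left < 0) -left else members[[left]],
             if (right < 0) -right else members[[right]])
    members[[m]] <- sort(mem)
  }
  lcv <- rep(NA_real_, n - 1)
  if (!is.null(cells)) {
    for (m in seq_len(n - 1)) lcv[m] <- lcv_percent(cells[members[[m]]])
  }
  nodes <- data.table::data.table(
    node = seq_len(n - 1),
    height = hc$height,
    n_members = lengths(members),
    lcv = lcv)
  nodes[, members := lapply(.SD$node, function(m) ids[members[[m]]])]
  structure(list(hc = hc, ids = ids, nodes = nodes,
                 member_idx = members), class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster tree over %d datasets (%d internal nodes)\n",
              length(x$ids), nrow(x$nodes)))
  print(x$nodes[, .(node, height = round(height, 4), n_members,
                    lcv = round(lcv, 3))])
  invisible(x)
}

#' Ward clustering from a CC distance matrix
#'
#' @param dmat Result of [cc_distance_matrix()].
#' @param datasets Optional dataset list (for per-node LCV annotation).
#' @return A `cluster_tree`: the `hclust` object plus a node table
#'   (height, members, LCV).
#' @export
hierarchical_cluster <- function(dmat, datasets = NULL) {
  D <- stats::as.dist(dmat$dist)
  hc <- stats::hclust(D, method = "ward.D2")
  cells <- NULL
  if (!is.null(datasets)) {
    idmap <- vapply(datasets, function(d) d$id, character(1))
    cells <- lapply(dmat$ids, function(id) datasets[[match(id, idmap)]]$cell)
  }
  build_cluster_tree(hc, dmat$ids, cells)
}

#' Cluster datasets by unit-cell variation
#'
#' Datasets are embedded as (a, b, c, face diagonals) vectors,
#' standardized to zero mean and unit variance over the cohort, and
#' clustered with Ward linkage on Euclidean distances; every node is
#' annotated with the LCV of its member cells.
#'
#' @param datasets List of [wedge_dataset()]s (>= 2), cells reduced.
#' @return A `cluster_tree`.
#' @export
cell_cluster <- function(datasets) {
  stopifnot(length(datasets) >= 2)
  ids <- vapply(datasets, function(d) d$id, character(1))
  cells <- lapply(datasets, function(d) niggli_reduce(d$cell)$cell)
  feat <- t(vapply(cells, function(cl) {
    c(cl[1:3], cell_face_diagonals(cl))
  }, numeric(6)))
  sds <- apply(feat, 2, stats::sd)
  sds[sds == 0] <- 1
  feat <- scale(feat, scale = sds)
  hc <- stats::hclust(stats::dist(feat), method = "ward.D2")
  build_cluster_tree(hc, ids, cells)
}

#' Remove datasets with extreme unit cells
#'
#' Rejects datasets whose reduced cell deviates from the
#' component-wise median by more than `tol_len` (relative, lengths) or
#' `tol_ang` (absolute degrees, angles).
#'
#' @param datasets List of [wedge_dataset()]s.
#' @param tol_len Relative length tolerance (default 0.1).
#' @param tol_ang Angle tolerance in degrees (default 3).
#' @return List with `kept` and `rejected` (data.frame id/reason).
#' @export
prefilter_cells <- function(datasets, tol_len = 0.1, tol_ang = 3) {
  stopifnot(length(datasets) >= 1)
  cells <- t(vapply(datasets, function(d) {
    as.numeric(niggli_reduce(d$cell)$cell)
  }, numeric(6)))
  med <- apply(cells, 2, stats::median)
  bad_len <- abs(sweep(cells[, 1:3, drop = FALSE], 2, med[1:3])) >
    tol_len * rep(med[1:3], each = nrow(cells))
  bad_ang <- abs(sweep(cells[, 4:6, drop = FALSE], 2, med[4:6])) > tol_ang
  bad <- rowSums(bad_len) + rowSums(bad_ang) > 0
  ids <- vapply(datasets, function(d) d$id, character(1))
  list(kept = datasets[!bad],
       rejected = data.frame(id = ids[bad],
                             reason = rep("cell deviates from cohort median",
                                          sum(bad)),
                             stringsAsFactors = FALSE))
}

#' Select clusters worth merging
#'
#' Pools the member datasets of every internal node, computes expected
#' completeness and multiplicity (before any outlier rejection), and
#' keeps the nodes exceeding both thresholds, sorted by descending
#' member count. A node and its qualifying ancestor are both kept.
#'
#' @param tree A `cluster_tree`.
#' @param datasets The datasets the tree was built over.
#' @param pg Merging [point_group()].
#' @param d_min High-resolution limit for the unique set; default the
#'   best resolution observed in the pooled data.
#' @param completeness_min Fraction in [0, 1] (default 0.9).
#' @param multiplicity_min Default 2.
#' @param anomalous Count Friedel pairs separately?
#' @return data.table of candidate nodes (node, n_members,
#'   completeness, multiplicity, lcv, members); empty with a warning
#'   when nothing qualifies.
#' @export
select_cluster_candidates <- function(tree, datasets, pg, d_min = NULL,
                                      completeness_min = 0.9,
                                      multiplicity_min = 2,
                                      anomalous = FALSE) {
  idmap <- vapply(datasets, function(d) d$id, character(1))
  stats_list <- lapply(seq_len(nrow(tree$nodes)), function(m) {
    ids <- tree$nodes$members[[m]]
    dss <- datasets[match(ids, idmap)]
    obs <- data.table::rbindlist(lapply(dss, function(ds) {
      r <- ds$reflections
      data.table::data.table(h = r$h, k = r$k, l = r$l)
    }))
    hkl <- as.matrix(obs)
    cell <- dss[[1]]$cell
    d <- d_spacing(hkl, cell)
    dmin_here <- if (is.null(d_min)) min(d) else d_min
    keep <- d >= dmin_here
    asu <- map_to_asu(hkl[keep, , drop = FALSE], pg, anomalous = anomalous)
    okey <- if (anomalous) asu$key * 2 + (asu$sign < 0) else asu$key
    uniq <- enumerate_unique(cell, pg, dmin_here, d_max = max(d),
                             anomalous = anomalous)
    n_obs <- sum(keep)
    n_unique_obs <- length(unique(okey))
    list(completeness = n_unique_obs / nrow(uniq),
         multiplicity = n_obs / n_unique_obs)
  })
  out <- data.table::copy(tree$nodes)
  out[, completeness := vapply(stats_list, `[[`, numeric(1), "completeness")]
  out[, multiplicity := vapply(stats_list, `[[`, numeric(1), "multiplicity")]
  cand <- out[completeness >= completeness_min &
                multiplicity >= multiplicity_min]
  if (nrow(cand) == 0) {
    warning("no cluster exceeds the completeness/multiplicity thresholds")
    return(cand)
  }
  cand[order(-n_members)]
}

#' Write a cluster tree as a Newick file
#'
#' Exports the dendrogram (with merge heights as branch lengths) in
#' Newick format via the ape package.
#'
#' @param tree A `cluster_tree`.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for Newick export")
  }
  phy <- ape::as.phylo(stats::as.hclust(tree$hc))
  ape::write.tree(phy, file = path)
  invisible(path)
}
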