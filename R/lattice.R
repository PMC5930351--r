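## Lattice grouping, metric symmetry and indexing-ambiguity operators.

#' Metric symmetry of a reduced cell
#'
#' Enumerate all reindexing operators (integer 3x3 matrices with
#' entries in [-2, 2] and det = +1 acting on hkl) that leave the
#' reciprocal metric invariant within a relative tolerance. These are
#' the proper rotations the lattice supports at that tolerance; a
#' pseudo-symmetric cell (e.g. orthorhombic with b close to c) gains
#' extra operators as the tolerance is loosened.
#'
#' @param cell A Niggli-reduced [unit_cell()].
#' @param tol Relative tolerance on reciprocal basis lengths and
#'   absolute tolerance on the cosines of the reciprocal angles
#'   (default 0.02, i.e. 2 percent).
#' @return A `point_group` whose `name` is inferred from the group
#'   structure and whose `ops` satisfy group closure.
#' @examples
#' metric_symmetry_ops(unit_cell(38.3, 78.6, 79.6, 90, 90, 90), tol = 0.02)
#' @export
metric_symmetry_ops <- function(cell, tol = 0.02) {
  cell <- as_unit_cell(cell)
  Gs <- cell_metric_reciprocal(cell)
  len <- sqrt(diag(Gs))
  ## candidate images for each reciprocal basis vector: integer vectors
  ## of matching length
  grid <- as.matrix(expand.grid(h = -2:2, k = -2:2, l = -2:2))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  vlen <- sqrt(rowSums((grid %*% Gs) * grid))
  cand <- lapply(1:3, function(i) {
    grid[abs(vlen - len[i]) / len[i] < tol, , drop = FALSE]
  })
  cosG <- Gs / outer(len, len)
  ops <- list()
  for (i1 in seq_len(nrow(cand[[1]]))) {
    v1 <- cand[[1]][i1, ]
    for (i2 in seq_len(nrow(cand[[2]]))) {
      v2 <- cand[[2]][i2, ]
      c12 <- (v1 %*% Gs %*% v2) / (len[1] * len[2])
      if (abs(c12 - cosG[1, 2]) >= tol) next
      for (i3 in seq_len(nrow(cand[[3]]))) {
        v3 <- cand[[3]][i3, ]
        m <- cbind(v1, v2, v3, deparse.level = 0)
        if (round(det(m)) != 1) next
        c13 <- (v1 %*% Gs %*% v3) / (len[1] * len[3])
        if (abs(c13 - cosG[1, 3]) >= tol) next
        c23 <- (v2 %*% Gs %*% v3) / (len[2] * len[3])
        if (abs(c23 - cosG[2, 3]) >= tol) next
        storage.mode(m) <- "integer"
        ops[[op_key(m)]] <- m
      }
    }
  }
  ops <- unname(ops)
  if (!is_group(ops)) {
    stop("metric symmetry operators do not close into a group at tol = ",
         tol, "; adjust the tolerance")
  }
  structure(list(name = pg_label(ops), ops = ops), class = "point_group")
}

#' Indexing-ambiguity operators
#'
#' When the point group used for merging is lower than the metric
#' symmetry of the lattice, several inequivalent indexing conventions
#' describe the same lattice. The distinct conventions are the right
#' cosets of the merging point group inside the metric-symmetry group;
#' one representative per coset is returned, identity first.
#'
#' @param cell A Niggli-reduced [unit_cell()].
#' @param merge_pg A [point_group()] (must be a subgroup of the metric
#'   symmetry at `tol`).
#' @param tol Metric tolerance passed to [metric_symmetry_ops()].
#' @return List of reindexing operators (integer 3x3 matrices); length
#'   equals the coset index |metric group| / |merge_pg|.
#' @examples
#' # orthorhombic cell with b ~ c: two indexing modes in point group 222
#' ops <- ambiguity_operators(unit_cell(38.3, 78.6, 79.6, 90, 90, 90),
#'                            point_group("222"), tol = 0.02)
#' @export
ambiguity_operators <- function(cell, merge_pg, tol = 0.02) {
  sym <- metric_symmetry_ops(cell, tol)
  sym_keys <- vapply(sym$ops, op_key, character(1))
  pg_keys <- vapply(merge_pg$ops, op_key, character(1))
  if (!all(pg_keys %in% sym_keys)) {
    stop("merge point group ", merge_pg$name,
         " is not a subgroup of the metric symmetry (order ",
         length(sym$ops), ") at tol = ", tol)
  }
  ## partition into right cosets H g: g1, g2 in same coset iff
  ## g1 g2^-1 in H
  remaining <- sym$ops
  reps <- list()
  while (length(remaining) > 0) {
    coset_of <- remaining[[1]]
    members <- Filter(function(g) {
      op_key(round(g %*% solve(coset_of))) %in% pg_keys
    }, remaining)
    ## canonical representative: fewest negative entries, then smallest
    ## flattened lexicographic order (keeps -h,l,k rather than h,-l,k
    ## for the b/c exchange coset)
    key_neg <- vapply(members, function(m) sum(m < 0), numeric(1))
    flat <- as.data.frame(t(vapply(members, as.integer, integer(9))))
    ord <- do.call(order, c(list(key_neg), flat))
    reps[[length(reps) + 1]] <- members[[ord[1]]]
    member_keys <- vapply(members, op_key, character(1))
    remaining <- Filter(function(g) !(op_key(g) %in% member_keys), remaining)
  }
  id_key <- op_key(op_identity())
  is_id <- vapply(reps, function(m) op_key(m) == id_key, logical(1))
  c(reps[is_id], reps[!is_id])
}

#' Group datasets by lattice
#'
#' Build an undirected graph on datasets with an edge wherever the
#' Niggli-reduced cells are similar, and extract connected components
#' sorted by decreasing population. Small components (fewer than
#' `min_group_size` members) are segregated into `small_groups`: they
#' usually stem from misindexed wedges.
#'
#' @param datasets List of `wedge_dataset` objects.
#' @param tol_len,tol_ang Similarity tolerances, see [cell_similar()].
#' @param min_group_size Smallest component reported as a usable group.
#' @return List with `groups` and `small_groups`; each group is a list
#'   with `member_ids`, `averaged_cell` and `symmetry_candidates`
#'   (a data.frame of point-group label, frequency, group order).
#' @export
build_lattice_groups <- function(datasets, tol_len = 0.1, tol_ang = 3,
                                 min_group_size = 2, sym_tol = 0.02) {
  stopifnot(length(datasets) >= 1)
  n <- length(datasets)
  red <- lapply(datasets, function(d) niggli_reduce(d$cell)$cell)
  ## union-find over the similarity graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (cell_similar(red[[i]], red[[j]], tol_len, tol_ang)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  make_group <- function(idx) {
    cells <- do.call(rbind, red[idx])
    avg <- as_unit_cell(colMeans(cells))
    labels <- vapply(idx, function(i) {
      pg_label(metric_symmetry_ops(red[[i]], sym_tol)$ops)
    }, character(1))
    list(member_ids = vapply(datasets[idx], function(d) d$id, character(1)),
         averaged_cell = avg,
         symmetry_candidates = symmetry_frequencies(labels))
  }
  comps <- split(seq_len(n), comp)
  comps <- comps[order(-lengths(comps))]
  big <- lengths(comps) >= min_group_size
  list(groups = lapply(comps[big], make_group),
       small_groups = lapply(comps[!big], make_group))
}

#' Tally point-group assignments across datasets
#'
#' @param labels Character vector of per-dataset point-group labels.
#' @return data.frame with columns `label`, `frequency`, `order`,
#'   sorted by descending frequency, ties broken by descending group
#'   order.
#' @export
symmetry_frequencies <- function(labels) {
  stopifnot(length(labels) > 0)
  tab <- table(labels)
  ord_of <- function(lab) {
    tryCatch(length(point_group(lab)$ops), error = function(e) {
      n <- suppressWarnings(as.integer(sub("^order", "", lab)))
      if (is.na(n)) 0L else n
    })
  }
  df <- data.frame(label = names(tab),
                   frequency = as.integer(tab),
                   order = vapply(names(tab), ord_of, integer(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  df[order(-df$frequency, -df$order), , drop = FALSE]
}
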