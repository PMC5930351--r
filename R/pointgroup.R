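## Reindexing operators and point groups on Miller indices.
##
## A reindexing operator is a unimodular (det = +1) integer 3x3 matrix m
## acting on the column vector (h, k, l). Only proper rotations are
## used: Friedel inversion is handled at merge time, not as an indexing
## mode.

#' Identity reindexing operator
#' @return 3x3 integer identity matrix.
#' @export
op_identity <- function() diag(3L)

op_key <- function(m) paste(as.integer(m), collapse = ",")

op_from_key <- function(key) {
  matrix(as.integer(strsplit(key, ",", fixed = TRUE)[[1]]), 3, 3)
}

#' Validate a reindexing operator
#'
#' @param m Integer 3x3 matrix acting on column vectors (h,k,l).
#' @return The matrix, invisibly, or an error.
#' @export
reindex_op <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3, 3)) || any(m != round(m))) {
    stop("reindex operator must be an integer 3x3 matrix")
  }
  storage.mode(m) <- "integer"
  if (round(det(m)) != 1L) stop("reindex operator must have det = +1")
  if (any(abs(m) > 2L)) stop("reindex operator entries must lie in [-2, 2]")
  m
}

#' Render a reindexing operator as an hkl triplet such as "-h,l,k"
#' @param m Reindexing operator.
#' @return Character scalar.
#' @export
op_hkl_string <- function(m) {
  sym <- c("h", "k", "l")
  rows <- vapply(1:3, function(i) {
    terms <- character(0)
    for (j in 1:3) {
      co <- m[i, j]
      if (co == 0) next
      pre <- if (co == 1) "" else if (co == -1) "-" else paste0(co, "*")
      if (length(terms) > 0 && co > 0) pre <- paste0("+", pre)
      terms <- c(terms, paste0(pre, sym[j]))
    }
    if (length(terms) == 0) "0" else paste(terms, collapse = "")
  }, character(1))
  paste(rows, collapse = ",")
}

## Multiplicative order of a rotation (smallest p with m^p = I).
op_order <- function(m) {
  acc <- diag(3)
  for (p in 1:6) {
    acc <- acc %*% m
    if (all(acc == diag(3))) return(p)
  }
  stop("operator order exceeds 6: not a crystallographic rotation")
}

## Close a generator set under multiplication.
group_closure <- function(gens, max_order = 48L) {
  ops <- list(op_identity())
  names(ops) <- op_key(ops[[1]])
  queue <- gens
  while (length(queue) > 0) {
    g <- queue[[1]]; queue <- queue[-1]
    k <- op_key(g)
    if (!is.null(ops[[k]])) next
    ops[[k]] <- g
    for (h in ops) {
      for (prod in list(g %*% h, h %*% g)) {
        pk <- op_key(prod)
        if (is.null(ops[[pk]])) queue <- c(queue, list(prod))
      }
    }
    if (length(ops) > max_order) stop("group closure exceeded maximal order")
  }
  unname(ops)
}

is_group <- function(ops) {
  keys <- vapply(ops, op_key, character(1))
  if (!(op_key(op_identity()) %in% keys)) return(FALSE)
  for (a in ops) {
    if (!(op_key(round(solve(a))) %in% keys)) return(FALSE)
    for (b in ops) {
      if (!(op_key(a %*% b) %in% keys)) return(FALSE)
    }
  }
  TRUE
}

#' Construct a point group of proper rotations on Miller indices
#'
#' Rotation groups for the standard settings used by the merging
#' engine. Trigonal and hexagonal groups assume the hexagonal basis
#' (gamma = 120 degrees); cubic and orthorhombic groups the standard
#' orthogonal basis.
#'
#' @param name One of "1", "2", "222", "4", "422", "3", "32", "6",
#'   "622", "23", "432".
#' @return A list with `name` and `ops` (list of integer 3x3 matrices,
#'   identity first) of class `point_group`.
#' @export
point_group <- function(name) {
  two_b   <- diag(c(-1L, 1L, -1L))
  two_c   <- diag(c(-1L, -1L, 1L))
  two_a   <- diag(c(1L, -1L, -1L))
  four_c  <- matrix(c(0L, 1L, 0L, -1L, 0L, 0L, 0L, 0L, 1L), 3, 3)
  # 3-fold about c in the hexagonal basis, acting on hkl: (-h-k, h, l)
  three_c <- matrix(c(-1L, 1L, 0L, -1L, 0L, 0L, 0L, 0L, 1L), 3, 3)
  two_hk  <- matrix(c(0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, -1L), 3, 3)
  three_d <- matrix(c(0L, 0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L), 3, 3)    # along 111
  gens <- switch(name,
    "1"   = list(),
    "2"   = list(two_b),
    "222" = list(two_a, two_b),
    "4"   = list(four_c),
    "422" = list(four_c, two_hk),
    "3"   = list(three_c),
    "32"  = list(three_c, two_hk),
    "6"   = list(three_c, two_c),
    "622" = list(three_c, two_c, two_hk),
    "23"  = list(two_a, two_b, three_d),
    "432" = list(two_a, two_b, three_d, four_c),
    stop("unknown point group: ", name)
  )
  ops <- group_closure(gens)
  ops <- ops[order(vapply(ops, function(m) op_key(m) != op_key(op_identity()),
                          logical(1)))]
  structure(list(name = name, ops = ops), class = "point_group")
}

#' @export
print.point_group <- function(x, ...) {
  cat(sprintf("point group %s (order %d)\n", x$name, length(x$ops)))
  invisible(x)
}

## Label an arbitrary rotation group by its abstract structure.
pg_label <- function(ops) {
  n <- length(ops)
  orders <- sort(vapply(ops, op_order, integer(1)))
  has <- function(p) p %in% orders
  if (n == 1) return("1")
  if (n == 2) return("2")
  if (n == 3) return("3")
  if (n == 4) return(if (has(4)) "4" else "222")
  if (n == 6) return(if (has(6)) "6" else "32")
  if (n == 8) return("422")
  if (n == 12) return(if (has(6)) "622" else "23")
  if (n == 24) return("432")
  paste0("order", n)
}
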