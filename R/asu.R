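## Mapping Miller indices to a canonical asymmetric-unit representative
## under a point group, with Friedel-pair bookkeeping.

ASU_BASE <- 1024
ASU_OFF <- 512

asu_encode <- function(hkl) {
  ((hkl[, 1] + ASU_OFF) * ASU_BASE + (hkl[, 2] + ASU_OFF)) * ASU_BASE +
    (hkl[, 3] + ASU_OFF)
}

asu_decode <- function(key) {
  l <- key %% ASU_BASE - ASU_OFF
  key <- (key - (l + ASU_OFF)) / ASU_BASE
  k <- key %% ASU_BASE - ASU_OFF
  h <- (key - (k + ASU_OFF)) / ASU_BASE - ASU_OFF
  cbind(h = h, k = k, l = l)
}

#' Map Miller indices to asymmetric-unit representatives
#'
#' Every reflection is replaced by a canonical representative of its
#' symmetry orbit: the lexicographically greatest orbit member under
#' the point group's proper rotations plus (always, so that Friedel
#' mates share a representative) the inversion. With `anomalous =
#' TRUE` the Friedel sign is recorded: +1 when the reflection reaches
#' its representative through a proper rotation, -1 when only through
#' inversion (centrosymmetric orbits get +1).
#'
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @param pg A [point_group()].
#' @param anomalous Keep track of Friedel signs?
#' @return List with `key` (numeric orbit key), `hkl` (n x 3 matrix of
#'   representatives) and `sign` (+1/-1 integer vector).
#' @export
map_to_asu <- function(hkl, pg, anomalous = FALSE) {
  hkl <- as.matrix(hkl)
  storage.mode(hkl) <- "integer"
  if (any(abs(hkl) >= ASU_OFF)) stop("Miller index magnitude >= 512 unsupported")
  n <- nrow(hkl)
  best_plus <- rep(-Inf, n)
  best_minus <- rep(-Inf, n)
  for (m in pg$ops) {
    tr <- hkl %*% t(m)
    keys <- asu_encode(tr)
    best_plus <- pmax(best_plus, keys)
    best_minus <- pmax(best_minus, asu_encode(-tr))
  }
  key <- pmax(best_plus, best_minus)
  sign <- ifelse(best_plus >= best_minus, 1L, -1L)
  if (!anomalous) sign <- rep(1L, n)
  list(key = key, hkl = asu_decode(key), sign = sign)
}

#' Enumerate the unique reflection set of a cell to a resolution limit
#'
#' All asymmetric-unit representatives with d in [d_min, d_max]. With
#' `anomalous = TRUE`, acentric Friedel mates are counted as two
#' distinct reflections (signed keys), matching the convention that
#' Friedel pairs are treated separately in multiplicity and CC
#' statistics.
#'
#' @param cell A [unit_cell()].
#' @param pg A [point_group()].
#' @param d_min High-resolution limit (Angstrom).
#' @param d_max Low-resolution limit (default Inf).
#' @param anomalous Count Friedel mates separately?
#' @return data.table with columns `key`, `sign`, `d`.
#' @export
enumerate_unique <- function(cell, pg, d_min, d_max = Inf, anomalous = FALSE) {
  cell <- as_unit_cell(cell)
  hmax <- ceiling(cell[1:3] / d_min)
  hmax <- pmin(hmax, ASU_OFF - 1)
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  d <- d_spacing(grid, cell)
  sel <- d >= d_min & d <= d_max
  grid <- grid[sel, , drop = FALSE]
  d <- d[sel]
  asu <- map_to_asu(grid, pg, anomalous = anomalous)
  dt <- data.table::as.data.table(list(key = asu$key, sign = asu$sign, d = d))
  if (anomalous) {
    ## centric reflections (orbit contains -h) appear once; acentric twice
    unique(dt, by = c("key", "sign"))
  } else {
    unique(dt, by = "key")
  }
}

#' Equal-volume resolution shell boundaries
#'
#' Shells equal in reciprocal-space volume, i.e. equidistant in
#' 1/d^3 between the low- and high-resolution limits.
#'
#' @param d_max,d_min Low/high resolution limits (Angstrom).
#' @param n_shells Number of shells.
#' @return Numeric vector of n_shells + 1 descending d boundaries.
#' @export
shell_boundaries <- function(d_max, d_min, n_shells = 10) {
  v <- seq(1 / d_max^3, 1 / d_min^3, length.out = n_shells + 1)
  v[1] <- 1 / d_max^3
  1 / v^(1 / 3)
}

shell_index <- function(d, bounds) {
  i <- findInterval(-d, -bounds, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(bounds) - 1L)
}
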