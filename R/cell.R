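#' Unit-cell parameters
#'
#' Construct a validated unit cell from the six lattice parameters.
#' Lengths are in Angstrom, angles in degrees. The cell must describe a
#' non-degenerate lattice: its metric tensor has to be positive definite.
#'
#' @param a,b,c Cell edge lengths (Angstrom), > 0.
#' @param alpha,beta,gamma Cell angles (degrees), in (0, 180).
#' @return An object of class `unit_cell`: a named numeric vector of
#'   length six.
#' @examples
#' uc <- unit_cell(38.3, 78.6, 79.6, 90, 90, 90)
#' cell_metric(uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(p))) stop("unit cell parameters must be finite")
  if (any(p[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) stop("cell angles must lie in (0, 180)")
  G <- metric_from_params(p)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("cell parameters give a non positive definite metric")
  structure(p, class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(x)
  x <- as.numeric(x)
  unit_cell(x[1], x[2], x[3], x[4], x[5], x[6])
}

metric_from_params <- function(p) {
  a <- p[[1]]; b <- p[[2]]; cc <- p[[3]]
  ca <- cos(p[[4]] * pi / 180); cb <- cos(p[[5]] * pi / 180)
  cg <- cos(p[[6]] * pi / 180)
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3, 3)
}

params_from_metric <- function(G) {
  a <- sqrt(G[1, 1]); b <- sqrt(G[2, 2]); cc <- sqrt(G[3, 3])
  al <- acos(G[2, 3] / (b * cc)) * 180 / pi
  be <- acos(G[1, 3] / (a * cc)) * 180 / pi
  ga <- acos(G[1, 2] / (a * b)) * 180 / pi
  unit_cell(a, b, cc, al, be, ga)
}

#' Real-space metric tensor of a cell
#'
#' @param cell A [unit_cell()].
#' @return Symmetric positive definite 3x3 matrix of basis-vector dot
#'   products (Angstrom^2).
#' @export
cell_metric <- function(cell) {
  metric_from_params(as_unit_cell(cell))
}

#' Reciprocal metric tensor (inverse of the real-space metric).
#' @param cell A [unit_cell()].
#' @return 3x3 matrix; `t(h) %*% G* %*% h` equals `1/d^2` for Miller
#'   index column `h`.
#' @export
cell_metric_reciprocal <- function(cell) {
  solve(cell_metric(cell))
}

#' Resolution of Miller indices
#'
#' d-spacings (Angstrom) for a set of Miller indices in a given cell.
#'
#' @param hkl Integer matrix with columns h, k, l (one row per reflection).
#' @param cell A [unit_cell()].
#' @return Numeric vector of d-spacings.
#' @export
d_spacing <- function(hkl, cell) {
  Gs <- cell_metric_reciprocal(cell)
  hkl <- as.matrix(hkl)
  inv_d2 <- rowSums((hkl %*% Gs) * hkl)
  1 / sqrt(inv_d2)
}

## s = sin(theta)/lambda = 1/(2 d); the Wilson falloff argument is s^2.
s2_of_d <- function(d) 1 / (4 * d * d)

#' Niggli cell reduction
#'
#' Reduce a unit cell to its Niggli form by the Krivy-Gruber algorithm
#' with numerically stabilised comparisons. The Niggli cell is the
#' canonical primitive cell (shortest basis vectors, standardised
#' angles), which makes lattices comparable independent of how they
#' were originally indexed.
#'
#' @param cell A [unit_cell()].
#' @param eps_rel Relative tolerance used in the reduction's equality
#'   comparisons.
#' @return A list with `cell` (the reduced [unit_cell()]) and
#'   `transform` (integer 3x3 matrix `M` with `t(M) %*% G %*% M` equal to
#'   the reduced metric, `G` being the input metric).
#' @examples
#' niggli_reduce(unit_cell(79.6, 38.3, 78.6, 90, 90, 90))
#' @export
niggli_reduce <- function(cell, eps_rel = 1e-6) {
  cell <- as_unit_cell(cell)
  G <- metric_from_params(cell)
  A <- G[1, 1]; B <- G[2, 2]; C <- G[3, 3]
  xi <- 2 * G[2, 3]; eta <- 2 * G[1, 3]; zeta <- 2 * G[1, 2]
  eps <- eps_rel * (A + B + C) / 3
  M <- diag(3)
  gt <- function(x, y) x > y + eps
  eq <- function(x, y) abs(x - y) <= eps
  apply_t <- function(Mi) M <<- M %*% Mi

  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    if (n_iter > 100L) stop("Niggli reduction did not converge in 100 steps")
    ## A1: order A <= B
    if (gt(A, B) || (eq(A, B) && gt(abs(xi), abs(eta)))) {
      tmp <- A; A <- B; B <- tmp
      tmp <- xi; xi <- eta; eta <- tmp
      apply_t(matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, 3))
    }
    ## A2: order B <= C (restart if applied)
    if (gt(B, C) || (eq(B, C) && gt(abs(eta), abs(zeta)))) {
      tmp <- B; B <- C; C <- tmp
      tmp <- eta; eta <- zeta; zeta <- tmp
      apply_t(matrix(c(-1, 0, 0, 0, 0, -1, 0, -1, 0), 3, 3))
      next
    }
    if (xi * eta * zeta > 0) {
      ## A3: make all angle terms positive
      i <- if (xi < 0) -1 else 1
      j <- if (eta < 0) -1 else 1
      k <- if (zeta < 0) -1 else 1
      xi <- abs(xi); eta <- abs(eta); zeta <- abs(zeta)
      apply_t(diag(c(i, j, k)))
    } else {
      ## A4: make all angle terms non-positive, det kept +1 via the
      ## flag on a zero-ish entry
      f <- c(if (gt(xi, 0)) -1 else 1,
             if (gt(eta, 0)) -1 else 1,
             if (gt(zeta, 0)) -1 else 1)
      if (prod(f) < 0) {
        z <- which(c(eq(xi, 0), eq(eta, 0), eq(zeta, 0)))
        if (length(z) == 0) stop("Niggli reduction sign step failed")
        f[z[1]] <- -f[z[1]]
      }
      xi <- -abs(xi); eta <- -abs(eta); zeta <- -abs(zeta)
      apply_t(diag(f))
    }
    if (gt(abs(xi), B) || (eq(xi, B) && gt(zeta, 2 * eta)) ||
        (eq(xi, -B) && gt(0, zeta))) {
      ## A5
      s <- sign(xi)
      apply_t(matrix(c(1, 0, 0, 0, 1, 0, 0, -s, 1), 3, 3))
      C <- B + C - xi * s
      eta <- eta - zeta * s
      xi <- xi - 2 * B * s
      next
    }
    if (gt(abs(eta), A) || (eq(eta, A) && gt(zeta, 2 * xi)) ||
        (eq(eta, -A) && gt(0, zeta))) {
      ## A6
      s <- sign(eta)
      apply_t(matrix(c(1, 0, 0, 0, 1, 0, -s, 0, 1), 3, 3))
      C <- A + C - eta * s
      xi <- xi - zeta * s
      eta <- eta - 2 * A * s
      next
    }
    if (gt(abs(zeta), A) || (eq(zeta, A) && gt(eta, 2 * xi)) ||
        (eq(zeta, -A) && gt(0, eta))) {
      ## A7
      s <- sign(zeta)
      apply_t(matrix(c(1, 0, 0, -s, 1, 0, 0, 0, 1), 3, 3))
      B <- A + B - zeta * s
      xi <- xi - eta * s
      zeta <- zeta - 2 * A * s
      next
    }
    sum5 <- xi + eta + zeta + A + B
    if (gt(0, sum5) || (eq(sum5, 0) && gt(2 * (A + eta) + zeta, 0))) {
      ## A8
      apply_t(matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 1), 3, 3))
      C <- A + B + C + xi + eta + zeta
      xi <- 2 * B + xi + zeta
      eta <- 2 * A + eta + zeta
      next
    }
    break
  }
  Gr <- matrix(c(A, zeta / 2, eta / 2,
                 zeta / 2, B, xi / 2,
                 eta / 2, xi / 2, C), 3, 3)
  storage.mode(M) <- "integer"
  list(cell = params_from_metric(Gr), transform = M)
}

#' Compare two Niggli-reduced cells
#'
#' Component-wise similarity test used to draw edges in the lattice
#' grouping graph: each reduced edge must agree within a relative length
#' tolerance and each angle within an absolute tolerance in degrees.
#'
#' @param c1,c2 Niggli-reduced [unit_cell()]s.
#' @param tol_len Relative tolerance on edge lengths (default 0.1).
#' @param tol_ang Absolute tolerance on angles in degrees (default 3).
#' @return Logical scalar; symmetric in its cell arguments.
#' @export
cell_similar <- function(c1, c2, tol_len = 0.1, tol_ang = 3) {
  c1 <- as_unit_cell(c1); c2 <- as_unit_cell(c2)
  assert_reduced(c1); assert_reduced(c2)
  len_ok <- abs(c1[1:3] - c2[1:3]) / pmin(c1[1:3], c2[1:3]) < tol_len
  ang_ok <- abs(c1[4:6] - c2[4:6]) < tol_ang
  all(len_ok) && all(ang_ok)
}

assert_reduced <- function(cell, tol = 1e-4) {
  red <- niggli_reduce(cell)$cell
  if (any(abs(red[1:3] - cell[1:3]) / cell[1:3] > tol) ||
      any(abs(red[4:6] - cell[4:6]) > 0.05)) {
    stop("cell is not Niggli-reduced; reduce it first")
  }
  invisible(cell)
}
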