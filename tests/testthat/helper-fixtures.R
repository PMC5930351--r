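## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

pseudo_ortho_cell <- function() unit_cell(38.3, 78.6, 79.6, 90, 90, 90)

## medium-resolution ground truth in the pseudo-ortho orthorhombic cell
pseudo_ortho_truth <- function() {
  fixture("pseudo_ortho_truth", function() {
    generate_truth(pseudo_ortho_cell(), point_group("222"), d_min = 3.0,
                   wilson_b = 20, seed = 101)
  })
}

## small, faster truth for scaling/merging unit tests
small_truth <- function() {
  fixture("small_truth", function() {
    generate_truth(unit_cell(30, 40, 50, 90, 90, 90), point_group("222"),
                   d_min = 3.5, wilson_b = 15, seed = 202)
  })
}

## a random valid cell with moderate geometry (used by the Niggli oracle)
## moderately skewed random cells: the original basis stays close
## enough to reduced that the +-3 coefficient bound of the brute-force
## oracle covers the reduction transform
random_cell <- function() {
  repeat {
    p <- c(sort(stats::runif(3, 8, 60)), stats::runif(3, 65, 115))
    cl <- tryCatch(unit_cell(p[1], p[2], p[3], p[4], p[5], p[6]),
                   error = function(e) NULL)
    if (!is.null(cl)) return(cl)
  }
}

## brute-force shortest non-coplanar lattice vector lengths: the oracle
## the Niggli-reduced edges are checked against
brute_force_shortest <- function(cell, bound = 3) {
  G <- cell_metric(cell)
  grid <- as.matrix(expand.grid(-bound:bound, -bound:bound, -bound:bound))
  grid <- grid[rowSums(abs(grid)) > 0, ]
  len <- sqrt(rowSums((grid %*% G) * grid))
  ord <- order(len)
  picked <- matrix(0, 0, 3)
  lens <- numeric(0)
  for (i in ord) {
    cand <- rbind(picked, grid[i, ])
    if (qr(cand)$rank == nrow(cand)) {
      picked <- cand
      lens <- c(lens, len[i])
    }
    if (nrow(picked) == 3) break
  }
  sort(lens)
}
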