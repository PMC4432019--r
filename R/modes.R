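#' Mass-weighted Hessian of the Tirion potential
#'
#' For each spring (i, j, k) with unit bond vector u, the 3x3 block
#' k * u u^T is added to the diagonal blocks (i,i), (j,j) and subtracted
#' from (i,j), (j,i); the result is symmetrically mass-weighted by
#' 1/sqrt(m_i m_j). At the equilibrium geometry this is exactly the matrix
#' of second derivatives of E = 1/2 sum k (|r_i - r_j| - d0_ij)^2.
#'
#' @param network an `elastic_network`.
#' @return dense symmetric 3N x 3N matrix.
#' @export
enm_hessian <- function(network) {
  xyz <- network$nodes$xyz
  m <- network$nodes$masses
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  e <- network$edges
  for (row in seq_len(nrow(e))) {
    i <- e$i[row]; j <- e$j[row]; k <- e$k[row]
    dv <- xyz[i, ] - xyz[j, ]
    dd <- sqrt(sum(dv^2))
    if (dd < 1e-9) stop("zero-length bond between beads ", i, " and ", j)
    u <- dv / dd
    blk <- k * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  w <- rep(1 / sqrt(m), each = 3)
  H <- H * tcrossprod(w)
  (H + t(H)) / 2
}

#' Normal modes of a Hessian
#'
#' Full dense eigendecomposition (ascending eigenvalues). Eigenvalues below
#' `zero_tol` times the largest are classified as rigid-body zero modes: 6
#' for a connected non-collinear system, 5 for two beads, 6 per component
#' otherwise. Frequencies are omega = sqrt(lambda) in arbitrary units.
#'
#' @param hessian symmetric matrix (3N x 3N for a spatial network, or any
#'   small positive semi-definite stiffness matrix, e.g. from [dimer_toy()]).
#' @param zero_tol relative zero-mode threshold (default 1e-8).
#' @param nodes optional `node_set` whose labels are carried along (needed
#'   by protein-only observables such as [mode_overlap()]).
#' @return object of class `mode_set`: list with `values` (ascending),
#'   `vectors` (orthonormal columns), `zero_count`, `n_beads`, `labels`.
#' @export
eigenmodes <- function(hessian, zero_tol = 1e-8, nodes = NULL) {
  if (max(abs(hessian - t(hessian))) > 1e-10 * max(1, max(abs(hessian))))
    stop("hessian must be symmetric")
  es <- eigen(hessian, symmetric = TRUE)
  vals <- rev(es$values)
  vecs <- es$vectors[, rev(seq_along(es$values)), drop = FALSE]
  vmax <- max(vals)
  if (vmax <= 0) stop("hessian has no positive eigenvalue")
  if (any(vals < -zero_tol * vmax))
    stop(sprintf(
      "hessian is not positive semidefinite (min eigenvalue %.3e, tol %.3e)",
      min(vals), -zero_tol * vmax))
  zero_count <- sum(vals < zero_tol * vmax)
  structure(list(values = vals, vectors = vecs, zero_count = zero_count,
                 n_beads = nrow(hessian) / 3,
                 labels = if (!is.null(nodes)) nodes$labels),
            class = "mode_set")
}

#' Normal modes of an elastic network
#'
#' Convenience wrapper: [enm_hessian()] then [eigenmodes()], carrying the
#' bead labels into the `mode_set`.
#'
#' @inheritParams enm_hessian
#' @inheritParams eigenmodes
#' @return a `mode_set`.
#' @export
normal_modes <- function(network, zero_tol = 1e-8) {
  eigenmodes(enm_hessian(network), zero_tol = zero_tol,
             nodes = network$nodes)
}

#' @export
print.mode_set <- function(x, ...) {
  nz <- length(x$values) - x$zero_count
  cat(sprintf("mode_set: %d modes (%d zero, %d vibrational), omega range [%.4g, %.4g]\n",
              length(x$values), x$zero_count, nz,
              sqrt(max(0, nonzero_values(x)[1])),
              sqrt(max(x$values))))
  invisible(x)
}

# nonzero (vibrational) eigenvalues / eigenvectors, ascending
nonzero_values <- function(modes) {
  modes$values[seq.int(modes$zero_count + 1L, length(modes$values))]
}
nonzero_vectors <- function(modes) {
  modes$vectors[, seq.int(modes$zero_count + 1L, length(modes$values)),
                drop = FALSE]
}

#' Sanity checks on a computed mode set
#'
#' Verifies eigenvector orthonormality, positive semidefiniteness, and that
#' the zero-mode count matches what the network's connectivity implies (6
#' per connected component for non-collinear geometries; 2N+1 for a single
#' collinear chain of N beads, which is 5 at N = 2). A zero-mode surplus is
#' reported as "atoms improperly connected".
#'
#' @param modes a `mode_set`.
#' @param network the `elastic_network` the modes came from.
#' @param tol orthonormality tolerance.
#' @return list of per-check results with overall `ok` flag.
#' @export
validate_modes <- function(modes, network, tol = 1e-8) {
  checks <- list()
  V <- modes$vectors
  ortho_resid <- max(abs(crossprod(V) - diag(ncol(V))))
  checks$orthonormal <- list(ok = ortho_resid <= max(tol, 1e-8),
                             residual = ortho_resid)
  checks$psd <- list(ok = min(modes$values) > -1e-8 * max(modes$values),
                     min_eigenvalue = min(modes$values))
  cr <- connectivity_report(network)
  collinear <- points_collinear(network$nodes$xyz)
  expected <- if (cr$n_components == 1L && collinear)
    2L * nrow(network$nodes$xyz) + 1L else 6L * cr$n_components
  msg <- NULL
  if (modes$zero_count > expected && cr$n_components == 1L)
    msg <- "unexpected zero-mode surplus"
  if (cr$n_components > 1L)
    msg <- sprintf("atoms improperly connected: %d components", cr$n_components)
  checks$zero_modes <- list(ok = modes$zero_count == expected,
                            observed = modes$zero_count, expected = expected,
                            message = msg)
  checks$ok <- checks$orthonormal$ok && checks$psd$ok &&
    (modes$zero_count == expected) && cr$n_components == 1L
  checks
}

#' Export eigenvalues (CSV) and eigenvectors (text matrix + JSON header)
#' @param modes a `mode_set`.
#' @param prefix output path prefix; writes `<prefix>_eigenvalues.csv`,
#'   `<prefix>_eigenvectors.txt`, `<prefix>_modes.json`.
#' @return vector of written paths, invisibly.
#' @export
write_modes <- function(modes, prefix) {
  p1 <- paste0(prefix, "_eigenvalues.csv")
  utils::write.csv(data.frame(mode = seq_along(modes$values),
                              eigenvalue = modes$values,
                              omega = sqrt(pmax(0, modes$values))),
                   p1, row.names = FALSE)
  p2 <- paste0(prefix, "_eigenvectors.txt")
  utils::write.table(modes$vectors, p2, row.names = FALSE, col.names = FALSE)
  p3 <- paste0(prefix, "_modes.json")
  jsonlite::write_json(list(n_beads = modes$n_beads,
                            zero_count = modes$zero_count,
                            n_modes = length(modes$values)),
                       p3, auto_unbox = TRUE)
  invisible(c(p1, p2, p3))
}
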