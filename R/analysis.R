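#' Predicted relative B-factors from an elastic network
#'
#' The standard ENM mobility profile: B_i is proportional to
#' sum_m |v_m(i)|^2 / lambda_m over the vibrational modes, i.e. the trace of
#' the 3x3 diagonal block of the Hessian pseudoinverse. Only the relative
#' profile is meaningful; the overall scale is arbitrary.
#'
#' @param modes a `mode_set` with bead labels.
#' @param protein_only restrict to protein beads (default TRUE).
#' @param n_modes number of vibrational modes to include (default all).
#' @return positive numeric vector, one value per bead.
#' @export
predicted_bfactors <- function(modes, protein_only = TRUE, n_modes = NULL) {
  lam <- nonzero_values(modes)
  n_modes <- n_modes %||% length(lam)
  V <- nonzero_vectors(modes)[, seq_len(n_modes), drop = FALSE]
  contrib <- V^2 %*% (1 / lam[seq_len(n_modes)])
  per_bead <- rowSums(matrix(contrib, ncol = 3, byrow = TRUE))
  if (protein_only && !is.null(modes$labels))
    per_bead <- per_bead[modes$labels$kind == "protein"]
  per_bead
}

#' Squared Pearson correlation between predicted and experimental B-factors
#'
#' Because the ENM B-profile is defined only up to an affine transformation,
#' agreement is scored as the squared Pearson correlation coefficient
#' (equivalently, the R-squared of the best-fit line with intercept).
#'
#' @param predicted,experimental numeric vectors, equal length >= 3.
#' @return R-squared in [0, 1].
#' @export
bfactor_r_squared <- function(predicted, experimental) {
  if (length(predicted) != length(experimental) || length(predicted) < 3L)
    stop("predicted and experimental must have equal length >= 3")
  if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(predicted, experimental)^2
}

#' Cumulative motion fraction of the softest m modes
#'
#' Thermal mean-square amplitude per mode scales as 1/lambda, so the
#' fraction of total motion carried by the first m vibrational modes
#' (ascending frequency) is sum_{i<=m} 1/lambda_i / sum_all 1/lambda_i.
#' The softest modes dominate: for a CAP-sized network the first 25 modes
#' carry roughly three quarters of the motion and the first 75 most of it.
#'
#' @param modes a `mode_set`.
#' @param m mode count, scalar or vector (1 .. number of vibrational modes).
#' @return fraction(s) in (0, 1].
#' @export
cumulative_motion <- function(modes, m) {
  lam <- nonzero_values(modes)
  if (any(m < 1L | m > length(lam))) stop("m out of range")
  cum <- cumsum(1 / lam) / sum(1 / lam)
  cum[m]
}

#' Eigenvector overlap matrix between two states
#'
#' Entry (a, b) is |v_a . v_b| for mode a of state X against mode b of
#' state Y, computed on the shared protein coordinates with each subvector
#' renormalized to unit length first (necessary when the states carry
#' different ligand beads). Rigid-body modes are skipped. A block-diagonal
#' low-frequency corner with mixing at higher modes is the signature of
#' ligand binding leaving the global soft modes intact while reshaping the
#' rest.
#'
#' @param modes_x,modes_y `mode_set`s sharing the same protein bead set.
#' @param n_modes number of vibrational modes per side (default 25).
#' @param skip number of leading modes to drop (default: each state's own
#'   zero-mode count, 6 for a connected network).
#' @return matrix of class `overlap_matrix` with entries in [0, 1].
#' @export
mode_overlap <- function(modes_x, modes_y, n_modes = 25L, skip = NULL) {
  Vx <- protein_mode_vectors(modes_x, skip)
  Vy <- protein_mode_vectors(modes_y, skip)
  if (nrow(Vx) != nrow(Vy))
    stop("states do not share a protein bead set")
  if (n_modes > ncol(Vx) || n_modes > ncol(Vy))
    stop("n_modes exceeds available vibrational modes")
  O <- abs(crossprod(Vx[, seq_len(n_modes), drop = FALSE],
                     Vy[, seq_len(n_modes), drop = FALSE]))
  structure(O, class = c("overlap_matrix", "matrix"))
}

# vibrational eigenvectors restricted to protein coordinates, renormalized
protein_mode_vectors <- function(modes, skip = NULL) {
  skip <- skip %||% modes$zero_count
  V <- modes$vectors[, seq.int(skip + 1L, ncol(modes$vectors)), drop = FALSE]
  if (!is.null(modes$labels)) {
    keep <- rep(modes$labels$kind == "protein", each = 3)
    V <- V[keep, , drop = FALSE]
  }
  nrm <- sqrt(colSums(V^2))
  sweep(V, 2, pmax(nrm, 1e-300), "/")
}

#' Residue cross-correlation map
#'
#' Normalized motional covariance between beads,
#' \deqn{C_{ij} = \frac{\sum_m v_m(i) \cdot v_m(j) / \lambda_m}
#'   {\sqrt{(\sum_m |v_m(i)|^2/\lambda_m)(\sum_m |v_m(j)|^2/\lambda_m)}},}
#' summed over the first `n_modes` vibrational modes. Entries lie in
#' [-1, 1] with unit diagonal; positive values are correlated motion,
#' negative anti-correlated.
#'
#' @param modes a `mode_set`.
#' @param n_modes vibrational modes included (default all).
#' @param protein_only restrict the map to protein beads (default TRUE).
#' @return symmetric matrix of class `correlation_map`.
#' @export
cross_correlation <- function(modes, n_modes = NULL, protein_only = TRUE) {
  lam <- nonzero_values(modes)
  n_modes <- n_modes %||% length(lam)
  if (n_modes < 1L || n_modes > length(lam)) stop("n_modes out of range")
  V <- nonzero_vectors(modes)[, seq_len(n_modes), drop = FALSE]
  W <- V %*% diag(1 / sqrt(lam[seq_len(n_modes)]), n_modes)
  G <- tcrossprod(W)                       # 3N x 3N covariance
  nb <- nrow(G) / 3
  # contract each 3x3 block to its trace
  tr <- matrix(0, nb, nb)
  for (d in 1:3) {
    sel <- seq(d, 3 * nb, by = 3)
    tr <- tr + G[sel, sel]
  }
  diag_tr <- diag(tr)
  C <- tr / sqrt(outer(diag_tr, diag_tr))
  if (protein_only && !is.null(modes$labels)) {
    keep <- modes$labels$kind == "protein"
    C <- C[keep, keep, drop = FALSE]
  }
  structure(C, class = c("correlation_map", "matrix"))
}

#' Mean cross-correlation within/between residue blocks
#'
#' Convenience for comparing liganded states: the mean map value over a
#' rectangular residue block (diagonal excluded when the blocks coincide).
#'
#' @param map a `correlation_map`.
#' @param rows,cols integer bead index vectors.
#' @return scalar mean correlation.
#' @export
block_mean_correlation <- function(map, rows, cols) {
  sub <- map[rows, cols, drop = FALSE]
  if (identical(rows, cols)) {
    sub <- sub[upper.tri(sub)]
    return(mean(sub))
  }
  mean(sub)
}

#' Export a matrix map as CSV with 1-based residue headers
#' @param map a matrix (`correlation_map` or `overlap_matrix`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  m <- as.matrix(map)
  dimnames(m) <- list(seq_len(nrow(m)), seq_len(ncol(m)))
  utils::write.csv(m, path)
  invisible(path)
}
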