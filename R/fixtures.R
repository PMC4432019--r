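#' Deterministic bead-set fixtures
#'
#' Small synthetic systems with known behaviour, used for testing and for
#' demonstrating the method without any structure download.
#'
#' @param distance,spacing Angstrom, > 0.
#' @param n number of beads (>= 2).
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_two_bead <- function(distance = 1) {
  stopifnot_scalar_num(distance, "distance", positive = TRUE)
  node_set(data.frame(chain = "A", resno = 1:2, kind = "protein",
                      name = "GLY"),
           rbind(c(0, 0, 0), c(distance, 0, 0)),
           source = sprintf("fixture two_bead(%g)", distance))
}

#' @rdname fixtures
#' @export
fixture_linear_chain <- function(n = 3, spacing = 5) {
  if (n < 2) stop("n must be >= 2")
  stopifnot_scalar_num(spacing, "spacing", positive = TRUE)
  node_set(data.frame(chain = "A", resno = seq_len(n), kind = "protein",
                      name = "GLY"),
           cbind((seq_len(n) - 1) * spacing, 0, 0),
           source = sprintf("fixture linear_chain(%d, %g)", n, spacing))
}

#' Randomized connected bead cloud
#'
#' Beads are grown sequentially: each new bead is placed 3-6 Angstrom from a
#' randomly chosen existing bead, inside the box and no closer than 2
#' Angstrom to any other bead, so the network is connected at any cutoff of
#' 6 Angstrom or more. Deterministic given `seed`.
#'
#' @param n number of beads.
#' @param box box edge, Angstrom.
#' @param seed integer seed.
#' @return a `node_set`.
#' @export
fixture_random_connected <- function(n = 20, box = 30, seed = 1) {
  if (n < 2) stop("n must be >= 2")
  stopifnot_scalar_num(box, "box", positive = TRUE)
  with_local_seed(seed, {
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- runif(3, box * 0.4, box * 0.6)
    for (i in 2:n) {
      repeat {
        anchor <- xyz[sample.int(i - 1L, 1L), ]
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- anchor + runif(1, 3, 6) * u
        if (any(cand < 0 | cand > box)) next
        d2 <- colSums((t(xyz[seq_len(i - 1L), , drop = FALSE]) - cand)^2)
        if (min(d2) >= 4) { xyz[i, ] <- cand; break }
      }
    }
    node_set(data.frame(chain = "A", resno = seq_len(n), kind = "protein",
                        name = "GLY"),
             xyz, source = sprintf("fixture random_connected(%d, %g, seed=%d)",
                                   n, box, seed))
  })
}

#' Two-site coupled-monomer toy with closed-form cooperativity
#'
#' The minimal scalar model of entropic allostery in a homodimer: each
#' monomer contributes one internal coordinate of stiffness `k`, the two are
#' coupled across the interface with `k_coupling`, and ligand binding
#' multiplies the bound monomer's internal stiffness by `alpha`. The three
#' state stiffness matrices are
#' \deqn{K_{apo} = \begin{pmatrix} k + k_c & -k_c \\ -k_c & k + k_c \end{pmatrix}}
#' and analogously with \eqn{\alpha k} on the bound diagonal(s). Because the
#' classical vibrational free energy depends only on frequency products, the
#' cooperativity ratio has the closed form
#' \deqn{K_2/K_1 = \sqrt{\det K_{apo} \det K_{holo2}} / \det K_{holo1}.}
#' For `k = 1, k_coupling = 1, alpha = 2` the determinants are 3, 5, 8 and
#' \eqn{K_2/K_1 = \sqrt{24}/5 \approx 0.9798} (weak positive cooperativity).
#' With `k_coupling = 0` the monomers are independent and the ratio is
#' exactly 1 for any `alpha`.
#'
#' @param k internal monomer stiffness (> 0).
#' @param k_coupling interface coupling stiffness (>= 0).
#' @param alpha stiffness multiplier on ligand binding (> 0).
#' @return object of class `dimer_toy` with the three 2x2 stiffness
#'   matrices (`K_apo`, `K_holo1`, `K_holo2`), the closed-form `k2_over_k1`
#'   and `ddg_over_kT`.
#' @export
dimer_toy <- function(k = 1, k_coupling = 1, alpha = 2) {
  stopifnot_scalar_num(k, "k", positive = TRUE)
  stopifnot_scalar_num(alpha, "alpha", positive = TRUE)
  stopifnot_scalar_num(k_coupling, "k_coupling")
  if (k_coupling < 0) stop("k_coupling must be >= 0")
  mk <- function(a1, a2)
    matrix(c(a1 * k + k_coupling, -k_coupling,
             -k_coupling, a2 * k + k_coupling), 2, 2)
  obj <- list(k = k, k_coupling = k_coupling, alpha = alpha,
              K_apo = mk(1, 1), K_holo1 = mk(alpha, 1),
              K_holo2 = mk(alpha, alpha))
  obj$ddg_over_kT <- dimer_toy_ddg(obj$K_apo, obj$K_holo1, obj$K_holo2)
  obj$k2_over_k1 <- exp(obj$ddg_over_kT)
  class(obj) <- "dimer_toy"
  obj
}

# closed form from 2x2 determinants
dimer_toy_ddg <- function(K00, K10, K11)
  0.5 * log(det(K00) * det(K11)) - log(det(K10))

#' @export
print.dimer_toy <- function(x, ...) {
  cat(sprintf("dimer_toy: k=%g k_coupling=%g alpha=%g  K2/K1 = %.6f\n",
              x$k, x$k_coupling, x$alpha, x$k2_over_k1))
  invisible(x)
}
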