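# Independent oracles, written from first principles and kept free of the
# package's own code paths.

# brute-force union-find over all pairwise distances
uf_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  length(unique(roots))
}

# Tirion potential energy for a displaced configuration
tirion_energy <- function(xyz0, edges, disp) {
  xyz <- xyz0 + matrix(disp, ncol = 3, byrow = TRUE)
  e <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    d0 <- sqrt(sum((xyz0[i, ] - xyz0[j, ])^2))
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e <- e + 0.5 * edges$k[r] * (d - d0)^2
  }
  e
}

# central finite-difference Hessian of the Tirion energy (unit masses)
fd_hessian <- function(xyz0, edges, h = 1e-4) {
  n3 <- 3 * nrow(xyz0)
  H <- matrix(0, n3, n3)
  for (a in seq_len(n3)) for (b in a:n3) {
    pp <- pm <- mp <- mm <- numeric(n3)
    pp[a] <- pp[a] + h; pp[b] <- pp[b] + h
    pm[a] <- pm[a] + h; pm[b] <- pm[b] - h
    mp[a] <- mp[a] - h; mp[b] <- mp[b] + h
    mm[a] <- mm[a] - h; mm[b] <- mm[b] - h
    v <- (tirion_energy(xyz0, edges, pp) - tirion_energy(xyz0, edges, pm) -
            tirion_energy(xyz0, edges, mp) + tirion_energy(xyz0, edges, mm)) /
      (4 * h^2)
    H[a, b] <- v; H[b, a] <- v
  }
  H
}

# cyclic Jacobi eigenvalue iteration, independent of LAPACK
jacobi_eigenvalues <- function(A, tol = 1e-12, max_sweeps = 100) {
  A <- as.matrix(A)
  n <- nrow(A)
  for (sweep in seq_len(max_sweeps)) {
    off <- sqrt(sum(A[upper.tri(A)]^2))
    if (off < tol) break
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      if (abs(A[p, q]) < tol / n^2) next
      theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
      t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
      if (theta == 0) t <- 1
      c <- 1 / sqrt(t^2 + 1); s <- t * c
      G <- diag(n); G[p, p] <- c; G[q, q] <- c; G[p, q] <- s; G[q, p] <- -s
      A <- t(G) %*% A %*% G
    }
  }
  sort(diag(A))
}

# small three-state system: a connected bead cloud plus one ligand bead per
# binding event, mimicking a dimer with two sites
mini_dimer_states <- function(seed = 11, cutoff = 6.5, base_spring = 1) {
  apo <- fixture_random_connected(12, 18, seed = seed)
  lig1 <- apo$xyz[3, ] + c(2.0, 1.0, 0.5)
  lig2 <- apo$xyz[9, ] + c(-1.5, 1.2, -0.8)
  add_bead <- function(ns, xyz, resno) {
    node_set(rbind(ns$labels,
                   data.frame(chain = "L", resno = resno, kind = "ligand",
                              name = "LIG")),
             rbind(ns$xyz, xyz), source = ns$source)
  }
  h1 <- add_bead(apo, lig1, 301L)
  h2 <- add_bead(h1, lig2, 302L)
  list(apo = build_network(apo, cutoff, base_spring),
       holo1 = build_network(h1, cutoff, base_spring),
       holo2 = build_network(h2, cutoff, base_spring))
}

# mode_set built directly from chosen eigenvalues (for formula-level tests)
manual_modes <- function(values, zero_count = 0L) {
  structure(list(values = values,
                 vectors = diag(length(values)),
                 zero_count = zero_count, n_beads = NA, labels = NULL),
            class = "mode_set")
}

# shared synthetic structure for slower tests (built once per test run)
synthetic_structure_cached <- local({
  cache <- NULL
  function(seed = 1L) {
    if (is.null(cache)) cache <<- synthetic_cap_structure(seed = seed)
    cache
  }
})
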