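#' Synthetic CAP-like homodimer structure
#'
#' Generates, entirely in code, a coarse C-alpha structure with the domain
#' architecture of the catabolite activator protein: two identical 210-residue
#' monomers related by a C2 axis; an N-terminal 138-residue ligand-binding
#' domain whose C-terminal segment (residues 112-136) is a long straight
#' helix forming the dimer interface; a C-terminal DNA-binding domain
#' (residues 139-210); and one cAMP ligand (22 heavy atoms) per monomer,
#' placed in a pocket between the body of the ligand-binding domain and the
#' interface helix. Everything else is a compact self-avoiding walk at
#' 3.8 Angstrom C-alpha spacing with protein-like packing density.
#'
#' This is a synthetic surrogate, not a crystal structure: it reproduces the
#' architecture the real protein is described by (domain sizes, dimer
#' interface, ligand placement) but none of its actual coordinates. The
#' B-factor column is likewise synthetic, generated from an inverse
#' contact-density heuristic with mild lognormal noise, the standard
#' qualitative relation between packing and crystallographic mobility.
#'
#' @param seed integer; the generator is fully deterministic given `seed`.
#' @return a `pdb_structure` (see [read_pdb()]) with chains A and B, residues
#'   1-210 each, plus two CMP HETATM groups.
#' @export
synthetic_cap_structure <- function(seed = 1L) {
  with_local_seed(seed, {
    mono <- synth_monomer()
    xyzA <- mono$xyz
    # C2 about the z axis: (x, y, z) -> (-x, -y, z)
    xyzB <- xyzA %*% diag(c(-1, -1, 1))
    ligA <- synth_camp(mono$pocket)
    ligB <- ligA %*% diag(c(-1, -1, 1))

    all_ca <- rbind(xyzA, xyzB)
    nc <- contact_counts(all_ca, 8)
    b <- 150 / (3 + nc) * exp(rnorm(nrow(all_ca), 0, 0.12))
    b <- b / mean(b) * 30

    n <- 210L
    atoms <- data.frame(
      record = c(rep("ATOM", 2L * n), rep("HETATM", 2L * nrow(ligA))),
      serial = seq_len(2L * n + 2L * nrow(ligA)),
      name = c(rep("CA", 2L * n), rep(camp_atom_names(), 2L)),
      altloc = "",
      resname = c(rep("ALA", 2L * n), rep("CMP", 2L * nrow(ligA))),
      chain = c(rep(c("A", "B"), each = n), rep(c("A", "B"), each = nrow(ligA))),
      resno = c(rep(seq_len(n), 2L), rep(301L, 2L * nrow(ligA))),
      insert = "",
      x = c(all_ca[, 1], ligA[, 1], ligB[, 1]),
      y = c(all_ca[, 2], ligA[, 2], ligB[, 2]),
      z = c(all_ca[, 3], ligA[, 3], ligB[, 3]),
      occupancy = 1,
      b = c(round(b, 2), rep(30, 2L * nrow(ligA))),
      element = c(rep("C", 2L * n), rep(camp_elements(), 2L)),
      stringsAsFactors = FALSE)
    structure(list(atoms = atoms,
                   source = sprintf("synthetic CAP-like homodimer (seed=%d)",
                                    seed)),
              class = "pdb_structure")
  })
}

# one monomer in the frame where the C2 axis is z and the partner sits at -x
synth_monomer <- function() {
  n <- 210L
  xyz <- matrix(NA_real_, n, 3)
  # interface helix, residues 112-136: ideal alpha-helix along z
  hres <- 112:136
  ang <- (seq_along(hres) - 1) * 100 * pi / 180
  xyz[hres, ] <- cbind(4.75 + 2.3 * cos(ang),
                       2.3 * sin(ang),
                       18 - 1.5 * (seq_along(hres) - 1))
  # ligand-binding domain body, residues 111..1 grown backwards from the helix
  xyz <- grow_walk(xyz, from = 112L, res = 111:1,
                   center = c(13, 0, 12), radius = 16, xmin = 1.2)
  # linker + DNA-binding domain, residues 137..210 grown from the helix end
  xyz <- grow_walk(xyz, from = 136L, res = 137:210,
                   center = c(13, 0, -24), radius = 13, xmin = 1.2)
  # cAMP pocket: between the domain body and the interface helix, nudged
  # toward the interface
  anchor <- colMeans(xyz[c(84:90, 121:127), ]) + c(-1.5, 0, 0)
  list(xyz = xyz, pocket = anchor)
}

# sequential self-avoiding growth with a progressively relaxed clash radius;
# the compactness bias (0.35 weight toward the domain centre) gives globular
# packing at protein-like density
grow_walk <- function(xyz, from, res, center, radius, xmin, bond = 3.8) {
  cur <- xyz[from, ]
  for (r in res) {
    placed <- !is.na(xyz[, 1])
    occ <- xyz[placed, , drop = FALSE]
    best <- NULL
    best_sep <- -Inf
    for (try in 1:160) {
      dmin <- c(3.8, 3.4, 3.0, 2.5)[min(4L, 1L + (try - 1L) %/% 40L)]
      u <- 0.35 * (center - cur) / max(1e-9, sqrt(sum((center - cur)^2))) +
        rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- cur + bond * u
      if (sqrt(sum((cand - center)^2)) > radius) next
      if (cand[1] < xmin) next
      sep <- sqrt(min(colSums((t(occ) - cand)^2)))
      if (sep > best_sep) { best_sep <- sep; best <- cand }
      if (sep >= dmin) break
    }
    if (is.null(best)) { # fully constrained corner: step toward the centre
      u <- (center - cur) / sqrt(sum((center - cur)^2))
      best <- cur + bond * u
    }
    xyz[r, ] <- best
    cur <- best
  }
  xyz
}

# 22 heavy atoms of cAMP arranged deterministically on a compact spiral
# around the pocket anchor (a shape proxy; only positions enter the network)
synth_camp <- function(anchor) {
  m <- 22L
  i <- seq_len(m)
  golden <- pi * (3 - sqrt(5))
  zf <- (2 * i - m - 1) / m
  r <- 2.2 * sqrt(pmax(0, 1 - zf^2)) * (0.55 + 0.45 * (i %% 3) / 2)
  th <- golden * i
  sweep(cbind(r * cos(th), r * sin(th), 2.2 * zf * 0.8), 2, anchor, `+`)
}

camp_atom_names <- function() {
  c("P", "O1P", "O2P", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'",
    "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4")
}

camp_elements <- function() {
  substr(gsub("[0-9']", "", camp_atom_names()), 1, 1)
}

contact_counts <- function(xyz, cutoff) {
  d <- pairwise_dist(xyz)
  rowSums(d <= cutoff) - 1L
}
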