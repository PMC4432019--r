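#' Ligand occupancy state of a homodimer
#'
#' @param tag one of `"apo"`, `"holo1"`, `"holo2"`.
#' @param ligands optional explicit list of ligand group identifiers, each a
#'   `c(chain, resno)` pair; length must match the tag (0, 1 or 2). When
#'   `NULL` the groups are auto-selected by [find_ligand_groups()].
#' @return object of class `ligand_state`.
#' @export
ligand_state <- function(tag = c("apo", "holo1", "holo2"), ligands = NULL) {
  tag <- match.arg(tag)
  n_expected <- c(apo = 0L, holo1 = 1L, holo2 = 2L)[[tag]]
  if (!is.null(ligands) && length(ligands) != n_expected)
    stop(sprintf("state '%s' requires exactly %d ligand group(s)", tag, n_expected))
  structure(list(tag = tag, ligands = ligands, n = n_expected),
            class = "ligand_state")
}

#' Locate candidate ligand groups in a structure
#'
#' HETATM records are grouped by (chain, resno, resname). By default groups
#' named CMP/CAMP (cyclic AMP) are considered and, when the protein has two
#' chains, the group nearest the centroid of each chain's ligand-binding
#' domain (residues `lbd_range`) is picked, one per chain, ordered by chain.
#'
#' @param structure a `pdb_structure`.
#' @param resnames HETATM residue names treated as the ligand.
#' @param explicit optional list of `c(chain, resno)` pairs overriding the
#'   automatic choice.
#' @param lbd_range residue range of the ligand-binding domain used to rank
#'   candidate groups (default 1:138).
#' @return list of data.frames of heavy atoms, one per ligand group, ordered
#'   by binding chain; each has attributes `chain` and `resno`.
#' @export
find_ligand_groups <- function(structure, resnames = c("CMP", "CAMP"),
                               explicit = NULL, lbd_range = 1:138) {
  a <- structure$atoms
  het <- a[a$record == "HETATM" & a$element != "H", , drop = FALSE]
  if (!is.null(explicit)) {
    groups <- lapply(explicit, function(g) {
      sub <- het[het$chain == g[1] & het$resno == as.integer(g[2]), , drop = FALSE]
      if (!nrow(sub)) stop(sprintf("ligand group %s:%s not found", g[1], g[2]))
      structure(sub, chain = g[1], resno = as.integer(g[2]))
    })
    return(groups)
  }
  het <- het[het$resname %in% resnames, , drop = FALSE]
  if (!nrow(het)) return(list())
  key <- paste(het$chain, het$resno, het$resname)
  groups <- lapply(split(het, key), function(sub)
    structure(sub, chain = sub$chain[1], resno = sub$resno[1]))
  # assign each protein chain's ligand-binding domain its nearest group
  ca <- a[a$record == "ATOM" & a$name == "CA", , drop = FALSE]
  chains <- unique(ca$chain)
  cent <- vapply(groups, function(g)
    colMeans(as.matrix(g[, c("x", "y", "z")])), numeric(3))
  chosen <- list()
  used <- rep(FALSE, length(groups))
  for (ch in chains) {
    lbd <- ca[ca$chain == ch & ca$resno %in% lbd_range, c("x", "y", "z")]
    if (!nrow(lbd)) next
    cc <- colMeans(as.matrix(lbd))
    d <- sqrt(colSums((cent - cc)^2))
    d[used] <- Inf
    if (all(!is.finite(d))) next
    j <- which.min(d)
    used[j] <- TRUE
    chosen[[ch]] <- groups[[j]]
  }
  unname(chosen)
}

#' Assemble the bead set for a given ligand state
#'
#' Protein beads are the C-alpha atoms of every chain, in chain/residue
#' order; holo states append ligand beads. Three ligand representations are
#' supported (the original work does not state how the bound nucleotide was
#' encoded in the network, so all three are exposed):
#' \describe{
#'   \item{centroid}{one bead per ligand at its heavy-atom centroid (default)}
#'   \item{heavy_atoms}{one bead per ligand heavy atom}
#'   \item{pocket_stiffen}{no extra beads; the returned apo-like `node_set`
#'     carries a `stiffen_pairs` attribute listing all pairs of pocket
#'     residues (residues with any heavy atom within `cutoff` of the ligand)
#'     whose connecting springs are to be stiffened}
#' }
#'
#' @param structure a `pdb_structure`.
#' @param state a `ligand_state` or a tag string.
#' @param ligand_model one of `"centroid"`, `"heavy_atoms"`, `"pocket_stiffen"`.
#' @param ligand_selector passed to [find_ligand_groups()] as `explicit`.
#' @param cutoff Angstrom; used only by `pocket_stiffen` to define the pocket.
#' @param holo1_group index (1 or 2) of the ligand group used for holo1;
#'   default 1, the ligand bound to the first chain in file order.
#' @return a `node_set`; under `pocket_stiffen` with a holo state it has a
#'   `stiffen_pairs` attribute (2-column matrix of bead indices).
#' @export
assemble_state <- function(structure, state,
                           ligand_model = c("centroid", "heavy_atoms",
                                            "pocket_stiffen"),
                           ligand_selector = NULL, cutoff = 8,
                           holo1_group = 1L) {
  ligand_model <- match.arg(ligand_model)
  if (is.character(state)) state <- ligand_state(state)
  a <- structure$atoms
  prot <- a[a$record == "ATOM", , drop = FALSE]
  if (!nrow(prot)) stop("structure has no protein ATOM records")
  prot <- prot[order(prot$chain, prot$resno, prot$insert), , drop = FALSE]
  reskey <- paste(prot$chain, prot$resno, prot$insert)
  has_ca <- tapply(prot$name == "CA", reskey, any)
  missing_ca <- names(has_ca)[!has_ca]
  if (length(missing_ca))
    warning(sprintf("%d residue(s) lack a CA atom and were skipped: %s",
                    length(missing_ca),
                    paste(utils::head(missing_ca, 5), collapse = ", ")))
  ca <- prot[prot$name == "CA", , drop = FALSE]
  labels <- data.frame(chain = ca$chain, resno = ca$resno, kind = "protein",
                       name = ca$resname, stringsAsFactors = FALSE)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  bvals <- ca$b

  groups <- list()
  if (state$n > 0L) {
    groups <- find_ligand_groups(structure, explicit = state$ligands %||%
                                   ligand_selector)
    if (length(groups) < state$n)
      stop(sprintf("state '%s' needs %d ligand group(s) but only %d found",
                   state$tag, state$n, length(groups)))
    groups <- if (state$n == 1L) groups[holo1_group] else groups[seq_len(2L)]
  }

  stiffen <- NULL
  if (state$n > 0L) {
    if (ligand_model == "centroid") {
      for (g in groups) {
        cen <- colMeans(as.matrix(g[, c("x", "y", "z")]))
        labels <- rbind(labels, data.frame(chain = attr(g, "chain"),
                                           resno = attr(g, "resno"),
                                           kind = "ligand",
                                           name = g$resname[1]))
        xyz <- rbind(xyz, cen)
        bvals <- c(bvals, NA)
      }
    } else if (ligand_model == "heavy_atoms") {
      for (g in groups) {
        labels <- rbind(labels, data.frame(chain = attr(g, "chain"),
                                           resno = attr(g, "resno"),
                                           kind = "ligand",
                                           name = g$name))
        xyz <- rbind(xyz, as.matrix(g[, c("x", "y", "z")]))
        bvals <- c(bvals, g$b)
      }
    } else { # pocket_stiffen: apo beads, per-ligand pocket pair lists
      heavy <- a[a$record == "ATOM" & a$element != "H", , drop = FALSE]
      pair_list <- list()
      for (g in groups) {
        lig_xyz <- as.matrix(g[, c("x", "y", "z")])
        pocket <- character(0)
        for (i in seq_len(nrow(heavy))) {
          d2 <- min(colSums((t(lig_xyz) - as.numeric(heavy[i, c("x", "y", "z")]))^2))
          if (d2 <= cutoff^2)
            pocket <- c(pocket, paste(heavy$chain[i], heavy$resno[i]))
        }
        beads <- which(paste(labels$chain, labels$resno) %in% unique(pocket))
        if (length(beads) >= 2L)
          pair_list[[length(pair_list) + 1L]] <- t(utils::combn(sort(beads), 2L))
      }
      if (length(pair_list)) {
        stiffen <- unique(do.call(rbind, pair_list))
      }
    }
  }
  rownames(xyz) <- NULL
  ns <- node_set(labels, xyz, masses = 1,
                 source = sprintf("%s [%s, %s]", structure$source, state$tag,
                                  ligand_model))
  attr(ns, "bfactors") <- bvals
  if (!is.null(stiffen)) attr(ns, "stiffen_pairs") <- stiffen
  attr(ns, "state") <- state$tag
  ns
}

#' Crystallographic B-factors of the protein beads of a state
#' @param nodes a `node_set` from [assemble_state()].
#' @return numeric vector (protein beads only).
#' @export
experimental_bfactors <- function(nodes) {
  b <- attr(nodes, "bfactors")
  if (is.null(b)) stop("node_set carries no B-factors")
  b[protein_beads(nodes)]
}
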