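#' Build the apo/holo1/holo2 elastic networks from one structure
#'
#' Assembles the three ligand states of the homodimer and builds a network
#' for each with a common cutoff and spring constant. Protein beads occupy
#' the same indices in every state (ligand beads are appended), so per-bead
#' perturbations can be applied consistently across states.
#'
#' @param structure a `pdb_structure`.
#' @param cutoff spring cutoff, Angstrom (default 8).
#' @param base_spring uniform spring constant (default 1).
#' @param ligand_model ligand representation, see [assemble_state()].
#' @param ligand_selector optional explicit ligand group list.
#' @param holo1_group which ligand group (1 or 2) binds first; which monomer
#'   binds first is not observable, so [allostery_both_choices()] can
#'   average over both.
#' @param stiffen_factor pocket-stiffening multiplier (pocket_stiffen only).
#' @return object of class `enm_states`: list with networks `apo`, `holo1`,
#'   `holo2` and the shared `protein_labels`.
#' @export
build_state_networks <- function(structure, cutoff = 8, base_spring = 1,
                                 ligand_model = "centroid",
                                 ligand_selector = NULL, holo1_group = 1L,
                                 stiffen_factor = 2) {
  mk <- function(tag) {
    ns <- assemble_state(structure, tag, ligand_model = ligand_model,
                         ligand_selector = ligand_selector, cutoff = cutoff,
                         holo1_group = holo1_group)
    build_network(ns, cutoff = cutoff, base_spring = base_spring,
                  stiffen_factor = stiffen_factor)
  }
  apo <- mk("apo"); h1 <- mk("holo1"); h2 <- mk("holo2")
  structure(list(apo = apo, holo1 = h1, holo2 = h2,
                 protein_labels = apo$nodes$labels,
                 cutoff = cutoff, base_spring = base_spring,
                 ligand_model = ligand_model),
            class = "enm_states")
}

#' @export
print.enm_states <- function(x, ...) {
  cat(sprintf("enm_states: cutoff %g A, k %g, ligand model '%s'\n",
              x$cutoff, x$base_spring, x$ligand_model))
  for (tag in c("apo", "holo1", "holo2")) print(x[[tag]])
  invisible(x)
}

#' Cooperativity averaged over both single-bound choices
#'
#' The structure does not say which monomer binds first, so the holo1 state
#' is ambiguous. This helper runs the full analysis once per choice of the
#' first-bound ligand group and returns both results plus the mean K2/K1.
#'
#' @inheritParams build_state_networks
#' @param ... passed to [allostery()].
#' @return list with `results` (one `allostery_result` per choice) and
#'   `k2_over_k1_mean`.
#' @export
allostery_both_choices <- function(structure, cutoff = 8, base_spring = 1,
                                   ligand_model = "centroid",
                                   ligand_selector = NULL, ...) {
  results <- lapply(1:2, function(g) {
    states <- build_state_networks(structure, cutoff = cutoff,
                                   base_spring = base_spring,
                                   ligand_model = ligand_model,
                                   ligand_selector = ligand_selector,
                                   holo1_group = g)
    allostery(states, ...)
  })
  list(results = results,
       k2_over_k1_mean = mean(vapply(results, `[[`, numeric(1),
                                     "k2_over_k1")))
}

#' Allosteric cooperativity of a three-state system
#'
#' End-to-end: normal modes of the three networks, convergence analysis of
#' K2/K1, per-mode entropies.
#'
#' @param states an `enm_states` object.
#' @param window,rel_tol convergence parameters, see [convergence_curve()].
#' @param require_connected error (with an "improperly connected"
#'   diagnostic) if any state network has more than one component.
#' @return an `allostery_result` with an extra `modes` element holding the
#'   three `mode_set`s.
#' @export
allostery <- function(states, window = 20L, rel_tol = 1e-3,
                      require_connected = TRUE) {
  for (tag in c("apo", "holo1", "holo2")) {
    cr <- connectivity_report(states[[tag]])
    if (require_connected && cr$n_components > 1L)
      stop(sprintf(
        "atoms improperly connected in %s network (%d components at cutoff %g A)",
        tag, cr$n_components, states[[tag]]$cutoff))
  }
  m0 <- normal_modes(states$apo)
  m1 <- normal_modes(states$holo1)
  m2 <- normal_modes(states$holo2)
  res <- convergence_curve(m0, m1, m2, window = window, rel_tol = rel_tol)
  res$modes <- list(apo = m0, holo1 = m1, holo2 = m2)
  res
}
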