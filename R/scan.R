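#' Default spring-scaling grid for the control scan
#'
#' 22 multiplicative steps evenly spaced in log2 between 1/4 and 4, with
#' the value closest to 1 replaced by exactly 1 so the wild-type column is
#' always part of the grid.
#'
#' @param n_steps number of factors (default 22).
#' @param log2_range half-range in log2 units (default 2, i.e. 1/4 .. 4).
#' @return sorted numeric vector containing exactly 1.
#' @export
default_factor_grid <- function(n_steps = 22L, log2_range = 2) {
  g <- 2^seq(-log2_range, log2_range, length.out = n_steps)
  g[which.min(abs(g - 1))] <- 1
  sort(unique(g))
}

#' Allosteric control map: K2/K1 under per-residue spring scaling
#'
#' For every protein residue r and every factor f in the grid, the springs
#' incident to r's bead are rescaled by f (k_R/k) in all three state
#' networks — a mutation exists in every liganded state, and in every chain
#' of the homodimer when `both_chains` is TRUE — and K2/K1 is recomputed.
#' The result maps which residues exert control over allostery at a
#' distance.
#'
#' @param states an `enm_states` object (or a [dimer_toy()], for which the
#'   "residues" are the two binding sites and the coupling spring and the
#'   closed-form determinant expression is used).
#' @param factors positive factor grid containing 1 (default
#'   [default_factor_grid()]).
#' @param residues residue numbers to scan (default: all residues of the
#'   first chain; with `both_chains` each number is perturbed in every
#'   chain simultaneously).
#' @param mode_policy `"full"` (K2/K1 at the shared full spectrum; exactly
#'   scale-invariant and convergence-free, the default), `"converged"`
#'   (the convergence-selection procedure), or a fixed integer mode count.
#' @param both_chains perturb the residue in all chains (default TRUE).
#' @param window,rel_tol convergence parameters when
#'   `mode_policy = "converged"`.
#' @param verbose log per-residue progress to stderr.
#' @return object of class `control_map`: list with `residues`, `factors`,
#'   `values` (residues x factors matrix of K2/K1), `wild_type`.
#' @export
control_map <- function(states, ...) UseMethod("control_map")

#' @rdname control_map
#' @param ... passed between methods.
#' @export
control_map.enm_states <- function(states, factors = default_factor_grid(),
                                   residues = NULL,
                                   mode_policy = "full", both_chains = TRUE,
                                   window = 20L, rel_tol = 1e-3,
                                   verbose = FALSE, ...) {
  if (any(factors <= 0)) stop("factors must be > 0")
  if (!any(factors == 1)) stop("the factor grid must contain 1.0")
  lab <- states$protein_labels
  chains <- unique(lab$chain)
  residues <- residues %||% sort(unique(lab$resno[lab$chain == chains[1]]))
  k2k1 <- function(nets) {
    m0 <- normal_modes(nets$apo)
    m1 <- normal_modes(nets$holo1)
    m2 <- normal_modes(nets$holo2)
    if (identical(mode_policy, "converged"))
      return(convergence_curve(m0, m1, m2, window, rel_tol)$k2_over_k1)
    mm <- min(length(nonzero_values(m0)), length(nonzero_values(m1)),
              length(nonzero_values(m2)))
    m <- if (identical(mode_policy, "full")) mm else as.integer(mode_policy)
    cooperativity_ratio(allosteric_free_energy(m0, m1, m2, m = m))
  }
  values <- matrix(NA_real_, length(residues), length(factors),
                   dimnames = list(residues, signif(factors, 6)))
  wt <- NULL
  for (ri in seq_along(residues)) {
    r <- residues[ri]
    bead_ref <- if (both_chains) as.character(r)
      else paste0(chains[1], ":", r)
    if (verbose)
      message(sprintf("scanning residue %s (%d/%d)", r, ri, length(residues)))
    for (fi in seq_along(factors)) {
      f <- factors[fi]
      val <- tryCatch({
        nets <- lapply(states[c("apo", "holo1", "holo2")],
                       perturb_site, bead = bead_ref, factor = f)
        k2k1(nets)
      }, error = function(e) {
        warning(sprintf("cell (residue %s, factor %g) failed: %s",
                        r, f, conditionMessage(e)))
        NA_real_
      })
      values[ri, fi] <- val
      if (f == 1 && is.null(wt) && is.finite(val)) wt <- val
    }
  }
  structure(list(residues = residues, factors = factors, values = values,
                 wild_type = wt, mode_policy = mode_policy,
                 both_chains = both_chains),
            class = "control_map")
}

#' @rdname control_map
#' @export
control_map.dimer_toy <- function(states, factors = default_factor_grid(),
                                  residues = c("site1", "coupling", "site2"),
                                  ...) {
  toy <- states
  scale_entry <- function(which, f) {
    k <- toy$k; kc <- toy$k_coupling; a <- toy$alpha
    kint <- c(1, 1)      # per-site internal stiffness multiplier
    fkc <- kc
    if (which == "coupling") fkc <- f * kc
    if (which == "site1") kint[1] <- f
    if (which == "site2") kint[2] <- f
    mk <- function(a1, a2) matrix(c(a1 * kint[1] * k + fkc, -fkc,
                                    -fkc, a2 * kint[2] * k + fkc), 2, 2)
    exp(dimer_toy_ddg(mk(1, 1), mk(a, 1), mk(a, a)))
  }
  values <- matrix(NA_real_, length(residues), length(factors),
                   dimnames = list(residues, signif(factors, 6)))
  for (ri in seq_along(residues))
    for (fi in seq_along(factors))
      values[ri, fi] <- scale_entry(residues[ri], factors[fi])
  structure(list(residues = residues, factors = factors, values = values,
                 wild_type = toy$k2_over_k1, mode_policy = "closed_form",
                 both_chains = FALSE),
            class = "control_map")
}

#' @export
print.control_map <- function(x, ...) {
  cat(sprintf("control_map: %d residues x %d factors, wild-type K2/K1 = %.6g\n",
              length(x$residues), length(x$factors), x$wild_type))
  invisible(x)
}

#' Classify residues by their influence on cooperativity
#'
#' A residue is an enhancer if some factor raises K2/K1 by at least
#' `threshold` relative to wild type (stronger negative cooperativity), a
#' suppressor if some factor lowers it by at least `threshold` (weaker
#' negative — possibly switching to positive — cooperativity), neutral
#' otherwise. A residue whose grid row crosses K2/K1 = 1 while the wild
#' type is above 1 is flagged as a sign switcher.
#'
#' @param map a `control_map`.
#' @param threshold relative change threshold (default 0.05).
#' @return list with `enhancer`, `suppressor`, `neutral`, `sign_switch`
#'   residue vectors and a `details` data.frame.
#' @export
classify_sites <- function(map, threshold = 0.05) {
  wt <- map$wild_type
  rel_up <- apply(map$values, 1, function(v) max(v / wt - 1, na.rm = TRUE))
  rel_dn <- apply(map$values, 1, function(v) max(1 - v / wt, na.rm = TRUE))
  crosses <- apply(map$values, 1, function(v)
    wt > 1 && any(v < 1, na.rm = TRUE))
  enh <- rel_up >= threshold
  sup <- rel_dn >= threshold
  list(enhancer = map$residues[enh],
       suppressor = map$residues[sup],
       neutral = map$residues[!enh & !sup],
       sign_switch = map$residues[crosses],
       details = data.frame(residue = map$residues,
                            max_rel_increase = rel_up,
                            max_rel_decrease = rel_dn,
                            sign_switch = crosses))
}

#' Predicted effect of a single-site spring mutation
#'
#' Models a point mutation as a strengthened (factor > 1) or weakened
#' (factor < 1) spring environment at one residue and reports the predicted
#' K2/K1 with a qualitative verdict relative to wild type.
#'
#' @param states an `enm_states` object.
#' @param site residue reference (number or `"chain:resno"`).
#' @param direction `"strengthen"` or `"weaken"`.
#' @param factor magnitude of the perturbation (> 1; inverted for
#'   weakening). Default 2.
#' @param mode_policy as in [control_map()].
#' @param both_chains perturb the site in all chains (default TRUE).
#' @return list with `k2_over_k1`, `wild_type`, `factor`, `verdict`.
#' @export
mutation_preset <- function(states, site,
                            direction = c("strengthen", "weaken"),
                            factor = 2, mode_policy = "full",
                            both_chains = TRUE) {
  direction <- match.arg(direction)
  if (factor < 1) stop("give factor > 1; use direction='weaken' to soften")
  f <- if (direction == "weaken") 1 / factor else factor
  cm <- control_map(states, factors = sort(unique(c(1, f))),
                    residues = if (is.numeric(site)) site else site,
                    mode_policy = mode_policy, both_chains = both_chains)
  wt <- cm$wild_type
  val <- cm$values[1, as.character(signif(f, 6))]
  verdict <- if (abs(val / wt - 1) < 1e-6) "no change"
    else if (wt > 1 && val < 1) "sign switch to positive cooperativity"
    else if (val > wt) "increased negative cooperativity"
    else "decreased negative cooperativity"
  list(k2_over_k1 = unname(val), wild_type = wt, factor = f,
       verdict = verdict)
}

#' Export a control map
#'
#' Long-format TSV (residue, factor, K2_over_K1, delta_vs_wt) and/or a
#' matrix CSV.
#'
#' @param map a `control_map`.
#' @param path output TSV path.
#' @param matrix_csv optional matrix CSV path.
#' @return `path`, invisibly.
#' @export
write_control_map <- function(map, path, matrix_csv = NULL) {
  long <- expand.grid(residue = map$residues, factor = map$factors,
                      KEEP.OUT.ATTRS = FALSE)
  long$K2_over_K1 <- as.vector(map$values)
  long$delta_vs_wt <- long$K2_over_K1 - map$wild_type
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_csv)) utils::write.csv(map$values, matrix_csv)
  invisible(path)
}
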