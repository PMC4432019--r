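#' Per-mode vibrational entropy change between two states
#'
#' Classical harmonic-oscillator entropy: pairing the vibrational modes of
#' the two states by ascending rank (zero modes removed), mode i contributes
#' \deqn{\Delta S_i / k_B = -\ln(\omega^{new}_i/\omega^{ref}_i)
#'   = -\tfrac12 \ln(\lambda^{new}_i/\lambda^{ref}_i).}
#' In the classical limit the h-bar omega / k_B T prefactors cancel, so only
#' frequency ratios matter and the arbitrary stiffness units of the network
#' drop out.
#'
#' @param modes_ref,modes_new `mode_set`s of the reference and new state.
#' @param m number of (nonzero) modes; default all shared modes.
#' @return numeric vector of length `m`: per-mode Delta S / k_B.
#' @export
mode_entropy_change <- function(modes_ref, modes_new, m = NULL) {
  lr <- nonzero_values(modes_ref)
  ln <- nonzero_values(modes_new)
  mmax <- min(length(lr), length(ln))
  m <- m %||% mmax
  if (m < 1L || m > mmax)
    stop(sprintf("m must be between 1 and %d shared nonzero modes", mmax))
  -0.5 * log(ln[seq_len(m)] / lr[seq_len(m)])
}

#' Allosteric free energy from three mode spectra
#'
#' The entropic allosteric free energy of the second binding event relative
#' to the first,
#' \deqn{\Delta\Delta G / k_B T = \sum_i \ln\omega_i^{holo2}
#'   + \sum_i \ln\omega_i^{apo} - 2 \sum_i \ln\omega_i^{holo1},}
#' summed over the first `m` vibrational modes of each state by rank.
#' Positive values mean the second binding is less favourable: negative
#' cooperativity, K2/K1 > 1.
#'
#' With `m = "full"` every vibrational mode of each state enters; this is
#' only balanced bookkeeping when the holo states add equal numbers of
#' ligand beads, i.e. N_holo2 + N_apo = 2 N_holo1 vibrational modes.
#'
#' @param modes_apo,modes_holo1,modes_holo2 `mode_set`s of the three states.
#' @param m mode count, or `"full"`.
#' @return Delta Delta G / k_B T (dimensionless scalar).
#' @export
allosteric_free_energy <- function(modes_apo, modes_holo1, modes_holo2,
                                   m = "full") {
  l0 <- nonzero_values(modes_apo)
  l1 <- nonzero_values(modes_holo1)
  l2 <- nonzero_values(modes_holo2)
  if (identical(m, "full")) {
    if (length(l0) + length(l2) != 2L * length(l1))
      stop(sprintf(paste0(
        "unbalanced mode counts at m='full' (apo %d + holo2 %d != 2 x holo1 %d);",
        " inconsistent state assembly"),
        length(l0), length(l2), length(l1)))
    return(0.5 * sum(log(l2)) + 0.5 * sum(log(l0)) - sum(log(l1)))
  }
  mmax <- min(length(l0), length(l1), length(l2))
  if (m < 1L || m > mmax) stop(sprintf("m must be in 1..%d", mmax))
  i <- seq_len(m)
  0.5 * sum(log(l2[i])) + 0.5 * sum(log(l0[i])) - sum(log(l1[i]))
}

#' Cooperativity ratio from the allosteric free energy
#'
#' K2/K1 = exp(Delta Delta G / k_B T): the ratio of the second to first
#' dissociation constants. Values above 1 indicate negative cooperativity.
#'
#' @param ddg_over_kT dimensionless allosteric free energy.
#' @return K2/K1.
#' @export
cooperativity_ratio <- function(ddg_over_kT) {
  if (!is.finite(ddg_over_kT)) stop("ddg_over_kT must be finite")
  exp(ddg_over_kT)
}

#' Cooperativity ratio versus included mode count, with convergence
#'
#' Computes K2/K1(m) for m = 1 .. (shared vibrational mode count) and finds
#' the smallest m whose following `window` values all stay within `rel_tol`
#' relative of K2/K1(m) — the mode count at which the ratio has converged
#' (typically beyond ~75 modes for CAP-sized networks, where the first 75
#' modes already carry ~90% of the motion).
#'
#' @param modes_apo,modes_holo1,modes_holo2 `mode_set`s of the three states.
#' @param window number of subsequent mode counts that must agree (default 20).
#' @param rel_tol relative agreement tolerance (default 1e-3).
#' @return object of class `allostery_result`: per-mode entropy changes
#'   (`delta_s1_per_mode`, `delta_s2_per_mode`, in k_B units), the
#'   convergence `curve` of K2/K1 over m, `converged_m` (integer or
#'   `"full"`), the converged `k2_over_k1` and `ddg_over_kT`, and the
#'   truncated-full-spectrum value `full_value` (m = shared mode count).
#' @export
convergence_curve <- function(modes_apo, modes_holo1, modes_holo2,
                              window = 20L, rel_tol = 1e-3) {
  l0 <- nonzero_values(modes_apo)
  l1 <- nonzero_values(modes_holo1)
  l2 <- nonzero_values(modes_holo2)
  mmax <- min(length(l0), length(l1), length(l2))
  i <- seq_len(mmax)
  inc <- 0.5 * log(l2[i]) + 0.5 * log(l0[i]) - log(l1[i])
  ddg_m <- cumsum(inc)
  curve <- exp(ddg_m)
  converged_m <- NA_integer_
  for (m in seq_len(mmax - window)) {
    win <- curve[m:(m + window)]
    if (all(abs(win / curve[m] - 1) < rel_tol)) { converged_m <- m; break }
  }
  if (is.na(converged_m)) {
    warning("K2/K1 did not converge before the end of the spectrum; ",
            "reporting the full-spectrum value")
    converged_m <- "full"
    ddg <- ddg_m[mmax]
  } else {
    ddg <- ddg_m[converged_m]
  }
  structure(list(
    delta_s1_per_mode = -0.5 * log(l1[i] / l0[i]),
    delta_s2_per_mode = -0.5 * log(l2[i] / l1[i]),
    ddg_over_kT = ddg,
    k2_over_k1 = exp(ddg),
    curve = curve,
    converged_m = converged_m,
    full_value = curve[mmax],
    window = window, rel_tol = rel_tol),
    class = "allostery_result")
}

#' @export
print.allostery_result <- function(x, ...) {
  cat(sprintf("allostery_result: K2/K1 = %.6g (converged at m = %s), ddG/kBT = %.6g\n",
              x$k2_over_k1, as.character(x$converged_m), x$ddg_over_kT))
  cat(sprintf("  full-spectrum (m = %d): K2/K1 = %.6g\n",
              length(x$curve), x$full_value))
  invisible(x)
}

#' Serialize an allostery result (JSON scalars + CSV curves)
#' @param x an `allostery_result`.
#' @param prefix path prefix; writes `<prefix>_allostery.json`,
#'   `<prefix>_convergence.csv`, `<prefix>_entropy_per_mode.csv`.
#' @return written paths, invisibly.
#' @export
write_allostery <- function(x, prefix) {
  p1 <- paste0(prefix, "_allostery.json")
  jsonlite::write_json(list(k2_over_k1 = x$k2_over_k1,
                            ddg_over_kT = x$ddg_over_kT,
                            converged_m = x$converged_m,
                            full_value = x$full_value),
                       p1, auto_unbox = TRUE, digits = NA)
  p2 <- paste0(prefix, "_convergence.csv")
  utils::write.csv(data.frame(m = seq_along(x$curve), k2_over_k1 = x$curve),
                   p2, row.names = FALSE)
  p3 <- paste0(prefix, "_entropy_per_mode.csv")
  utils::write.csv(data.frame(mode = seq_along(x$delta_s1_per_mode),
                              delta_s1_kB = x$delta_s1_per_mode,
                              delta_s2_kB = x$delta_s2_per_mode),
                   p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
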