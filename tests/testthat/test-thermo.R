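test_that("per-mode entropy change follows -0.5 log(lambda ratio)", {
  m_ref <- manual_modes(c(1, 4))
  expect_equal(mode_entropy_change(m_ref, m_ref), c(0, 0))
  m_new <- manual_modes(c(4, 4))
  expect_equal(mode_entropy_change(m_ref, m_new), c(-log(2), 0))
  expect_equal(mode_entropy_change(m_ref, m_new, m = 1), -log(2))
  expect_error(mode_entropy_change(m_ref, m_new, m = 3), "between 1 and")
})

test_that("identical states give zero allosteric free energy and K2/K1 = 1", {
  net <- build_network(fixture_random_connected(10, 18, seed = 2), 7)
  m <- normal_modes(net)
  expect_equal(allosteric_free_energy(m, m, m), 0)
  res <- convergence_curve(m, m, m)
  expect_equal(unname(res$curve), rep(1, length(res$curve)))
  expect_equal(res$converged_m, 1L)
  expect_equal(res$k2_over_k1, 1)
})

test_that("the coupled-dimer toy reproduces its closed-form cooperativity", {
  toy <- dimer_toy(k = 1, k_coupling = 1, alpha = 2)
  expect_equal(det(toy$K_apo), 3)
  expect_equal(det(toy$K_holo1), 5)
  expect_equal(det(toy$K_holo2), 8)
  expect_equal(toy$ddg_over_kT, 0.5 * log(24 / 25), tolerance = 1e-12)
  expect_equal(toy$k2_over_k1, sqrt(24) / 5, tolerance = 1e-12)
  # same numbers through the generic mode machinery
  m0 <- eigenmodes(toy$K_apo)
  m1 <- eigenmodes(toy$K_holo1)
  m2 <- eigenmodes(toy$K_holo2)
  ddg <- allosteric_free_energy(m0, m1, m2, m = 2)
  expect_equal(ddg, toy$ddg_over_kT, tolerance = 1e-10)
  expect_equal(cooperativity_ratio(ddg), toy$k2_over_k1, tolerance = 1e-10)
})

test_that("uncoupled monomers are exactly non-cooperative", {
  for (alpha in c(0.5, 2, 7)) {
    toy <- dimer_toy(k = 1.3, k_coupling = 0, alpha = alpha)
    expect_equal(toy$k2_over_k1, 1, tolerance = 1e-14)
  }
})

test_that("cooperativity_ratio is the exponential map", {
  expect_equal(cooperativity_ratio(0), 1)
  expect_equal(cooperativity_ratio(log(2)), 2)
  expect_equal(cooperativity_ratio(0.5 * log(24 / 25)), sqrt(24) / 5)
  expect_error(cooperativity_ratio(NaN), "finite")
})

test_that("K2/K1 at fixed mode count is invariant under uniform spring scaling", {
  for (c_scale in c(0.5, 3)) {
    s1 <- mini_dimer_states(seed = 11, base_spring = 1)
    s2 <- mini_dimer_states(seed = 11, base_spring = c_scale)
    k2k1 <- function(s, m) {
      cooperativity_ratio(allosteric_free_energy(
        normal_modes(s$apo), normal_modes(s$holo1), normal_modes(s$holo2),
        m = m))
    }
    for (m in c(5, 15, 28)) {
      expect_equal(k2k1(s1, m), k2k1(s2, m), tolerance = 1e-9)
    }
  }
})

test_that("exchange symmetry holds exactly on a mirror-symmetric dimer", {
  # two identical monomer blocks relating by inversion, ligand on either one
  blk <- fixture_random_connected(6, 10, seed = 5)$xyz
  xyz_a <- sweep(blk, 2, c(12, 0, 0), `+`)
  xyz_b <- -xyz_a
  lab <- data.frame(chain = rep(c("A", "B"), each = 6), resno = rep(1:6, 2),
                    kind = "protein", name = "GLY")
  prot <- rbind(xyz_a, xyz_b)
  lig_a <- xyz_a[2, ] + c(2, 1, 0)
  lig_b <- -lig_a
  mk <- function(extra_xyz, extra_n) {
    labs <- lab
    if (length(extra_n))
      labs <- rbind(lab, data.frame(chain = "L", resno = extra_n,
                                    kind = "ligand", name = "LIG"))
    build_network(node_set(labs, rbind(prot, extra_xyz)), cutoff = 40)
  }
  apo <- mk(NULL, integer(0))
  h1_first <- mk(rbind(lig_a), 301L)
  h1_second <- mk(rbind(lig_b), 301L)
  h2 <- mk(rbind(lig_a, lig_b), c(301L, 302L))
  k2k1 <- function(h1) cooperativity_ratio(allosteric_free_energy(
    normal_modes(apo), normal_modes(h1), normal_modes(h2), m = 20))
  expect_equal(k2k1(h1_first), k2k1(h1_second), tolerance = 1e-9)
})

test_that("either single-bound choice gives the same answer on a C2 dimer", {
  both <- allostery_both_choices(synthetic_structure_cached())
  k <- vapply(both$results, `[[`, numeric(1), "k2_over_k1")
  expect_equal(k[1], k[2], tolerance = 1e-9)
  expect_equal(both$k2_over_k1_mean, mean(k))
})

test_that("the ratio equals the frequency product formula", {
  s <- mini_dimer_states(seed = 14)
  m0 <- normal_modes(s$apo); m1 <- normal_modes(s$holo1)
  m2 <- normal_modes(s$holo2)
  m <- 20
  l0 <- m0$values[m0$zero_count + seq_len(m)]
  l1 <- m1$values[m1$zero_count + seq_len(m)]
  l2 <- m2$values[m2$zero_count + seq_len(m)]
  prod_formula <- prod(sqrt(l2) * sqrt(l0) / l1)
  expect_equal(cooperativity_ratio(allosteric_free_energy(m0, m1, m2, m = m)),
               prod_formula, tolerance = 1e-10)
})

test_that("full-spectrum bookkeeping requires balanced mode counts", {
  s <- mini_dimer_states(seed = 11)
  m0 <- normal_modes(s$apo); m1 <- normal_modes(s$holo1)
  m2 <- normal_modes(s$holo2)
  # balanced: N_apo + N_holo2 = 2 N_holo1 (one ligand bead per event)
  expect_silent(allosteric_free_energy(m0, m1, m2, m = "full"))
  expect_error(allosteric_free_energy(m0, m1, m1, m = "full"), "unbalanced")
})

test_that("convergence analysis reports a stable plateau and serializes", {
  s <- mini_dimer_states(seed = 11)
  res <- convergence_curve(normal_modes(s$apo), normal_modes(s$holo1),
                           normal_modes(s$holo2), window = 5, rel_tol = 0.05)
  expect_s3_class(res, "allostery_result")
  expect_equal(res$k2_over_k1, exp(res$ddg_over_kT), tolerance = 1e-12)
  expect_equal(res$full_value, res$curve[length(res$curve)])
  expect_true(res$k2_over_k1 > 0)
  if (is.numeric(res$converged_m)) {
    win <- res$curve[res$converged_m:(res$converged_m + 5)]
    expect_true(all(abs(win / res$curve[res$converged_m] - 1) < 0.05))
  }
  prefix <- file.path(withr::local_tempdir(), "toy")
  paths <- write_allostery(res, prefix)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_equal(js$k2_over_k1, res$k2_over_k1, tolerance = 1e-12)
})
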