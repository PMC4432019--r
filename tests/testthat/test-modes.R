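test_that("two-bead Hessian has the analytic single-bond form", {
  H <- enm_hessian(build_network(fixture_two_bead(1), 8))
  expect_equal(dim(H), c(6, 6))
  expect_equal(H[1, 1], 1)
  expect_equal(H[4, 4], 1)
  expect_equal(H[1, 4], -1)
  # nothing off the bond axis
  expect_equal(H[2:3, ], matrix(0, 2, 6))
  expect_true(isSymmetric(H))
})

test_that("uniform translations are exact zero-energy directions", {
  for (seed in c(3, 8)) {
    net <- build_network(fixture_random_connected(10, 20, seed = seed), 7)
    H <- enm_hessian(net)
    for (d in 1:3) {
      t_vec <- rep(0, 30); t_vec[seq(d, 30, by = 3)] <- 1
      expect_lt(max(abs(H %*% t_vec)), 1e-12)
    }
  }
})

test_that("Hessian matches central finite differences of the Tirion energy", {
  net <- build_network(fixture_random_connected(8, 15, seed = 3), 7)
  H <- enm_hessian(net)
  H_fd <- fd_hessian(net$nodes$xyz, net$edges)
  expect_equal(H, H_fd, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("Hessian agrees with an independently built ANM Hessian", {
  net <- build_network(fixture_random_connected(9, 16, seed = 6), 7.5)
  H <- enm_hessian(net)
  H_ref <- bio3d::build.hessian(
    as.numeric(t(net$nodes$xyz)),
    pfc.fun = function(r) ifelse(r <= 7.5, 1, 0))
  expect_equal(H, unname(as.matrix(H_ref)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("mass weighting divides blocks by sqrt(m_i m_j)", {
  ns <- fixture_two_bead(1)
  ns$masses <- c(4, 9)
  H <- enm_hessian(build_network(ns, 8))
  expect_equal(H[1, 1], 1 / 4)
  expect_equal(H[4, 4], 1 / 9)
  expect_equal(H[1, 4], -1 / 6)
})

test_that("two beads give the hand-computed spectrum {2} with 5 zero modes", {
  modes <- normal_modes(build_network(fixture_two_bead(1), 8))
  expect_equal(modes$zero_count, 5)
  nz <- modes$values[6]
  expect_equal(nz, 2, tolerance = 1e-12)
  expect_equal(sort(modes$values)[1:5], rep(0, 5), tolerance = 1e-10)
})

test_that("zero-mode count is 6 per connected component once the network is rigid", {
  con <- normal_modes(build_network(fixture_random_connected(12, 20, seed = 5), 9))
  expect_equal(con$zero_count, 6)
  # two clusters far apart: 12 rigid modes
  a <- fixture_random_connected(6, 12, seed = 1)
  b <- fixture_random_connected(6, 12, seed = 2)
  lab <- data.frame(chain = rep(c("A", "B"), each = 6), resno = rep(1:6, 2),
                    kind = "protein", name = "GLY")
  two <- node_set(lab, rbind(a$xyz, b$xyz + 100))
  modes <- normal_modes(build_network(two, 13))
  expect_equal(modes$zero_count, 12)
  # an undercrosslinked (tree-like) network keeps extra floppy zero modes
  floppy <- normal_modes(build_network(fixture_random_connected(12, 20, seed = 5), 7))
  expect_gt(floppy$zero_count, 6)
})

test_that("eigenvalues scale linearly with a uniform spring constant", {
  ns <- fixture_random_connected(10, 18, seed = 4)
  v1 <- normal_modes(build_network(ns, 7, base_spring = 1))$values
  v3 <- normal_modes(build_network(ns, 7, base_spring = 3))$values
  expect_equal(v3, 3 * v1, tolerance = 1e-10)
})

test_that("spectrum sums to the Hessian trace and vectors are orthonormal", {
  net <- build_network(fixture_random_connected(11, 20, seed = 9), 7)
  H <- enm_hessian(net)
  modes <- eigenmodes(H, nodes = net$nodes)
  expect_equal(sum(modes$values), sum(diag(H)), tolerance = 1e-8)
  V <- modes$vectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
})

test_that("small-system eigenvalues agree with a Jacobi-rotation oracle", {
  for (seed in c(2, 7)) {
    net <- build_network(fixture_random_connected(6, 12, seed = seed), 7)
    H <- enm_hessian(net)
    expect_equal(eigenmodes(H)$values, jacobi_eigenvalues(H), tolerance = 1e-8)
  }
})

test_that("eigenmodes rejects asymmetric and indefinite input", {
  expect_error(eigenmodes(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  expect_error(eigenmodes(matrix(c(1, 0, 0, -1), 2, 2)), "semidefinite")
})

test_that("validate_modes passes healthy fixtures and flags corruption", {
  net <- build_network(fixture_random_connected(10, 18, seed = 12), 9)
  modes <- normal_modes(net)
  rep_ok <- validate_modes(modes, net)
  expect_true(rep_ok$ok)
  bad <- modes
  bad$vectors[, 7] <- bad$vectors[, 7] * 2
  expect_false(validate_modes(bad, net)$orthonormal$ok)
  # disconnected network: zero-mode surplus reported as improper connectivity
  far <- node_set(data.frame(chain = "A", resno = 1:4, kind = "protein",
                             name = "GLY"),
                  rbind(c(0, 0, 0), c(4, 0, 0), c(50, 0, 0), c(54, 3, 0)))
  net2 <- build_network(far, 8)
  rep2 <- validate_modes(normal_modes(net2), net2)
  expect_false(rep2$ok)
  expect_match(rep2$zero_modes$message, "improperly connected")
})
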