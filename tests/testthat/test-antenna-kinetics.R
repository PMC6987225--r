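test_that("rate derivation reproduces the cellular scenario", {
  r <- derive_rates(antenna_physical(), reconcile = TRUE)
  expect_equal(r$k1, 1e-3)
  expect_equal(r$km1, 30)   # volume ratio 1000/0.033, quoted at 2 s.f.
  expect_equal(r$km2, 100)
  expect_equal(r$km3, 10)
  expect_equal(r$k_SD, 200 * 1000 / 2500)        # 80 1/s off the specific site
  expect_equal(r$k_DS, 80 * (3e4 * 100) / (10 * 2.7e7))  # 80/90
  expect_equal(r$k2, 900 * r$k3)
  expect_error(antenna_physical(antenna_volume_um3 = 0), "positive")
  expect_error(antenna_physical(kd3_M = 1e-6, kd2_M = 1e-7), "kd3")
})

test_that("literal published rates are exposed but flagged inconsistent", {
  expect_warning(r <- derive_rates(reconcile = FALSE), "detailed balance")
  expect_equal(r$k3, 1e7)
  expect_equal(r$k2, 9e9)
  expect_gt(detailed_balance_residual(r), 100)
})

test_that("the generator matrix conserves probability by construction", {
  r <- derive_rates()
  Q <- rate_matrix(r)
  expect_equal(max(abs(colSums(Q))), 0, tolerance = 1e-12 * max(abs(Q)))
  expect_equal(Q["A_F", "A_F"], -(r$km1 + r$k2 + r$k3))
  expect_equal(Q["SB", "D_eg"], r$k_DS)
  expect_equal(Q["D_eg", "SB"], r$k_SD)
  z <- antenna_rates(0, 0, 0, 0, 0, 0, 0, 0)
  expect_true(all(rate_matrix(z) == 0))
  expect_error(antenna_rates(-1, 1, 1, 1, 1, 1, 1, 1), ">= 0")
})

test_that("spectral solution recovers closed forms", {
  # two-state closed exchange
  a <- 3; b <- 7
  Q <- matrix(c(-a, a, b, -b), 2, 2,
              dimnames = rep(list(c("off", "on")), 2))
  sol <- solve_kinetics(Q)
  expect_equal(sol$eigenvalues[2], a + b)
  expect_equal(unname(sol$stationary), c(b, a) / (a + b))

  # symmetric ring: uniform stationary distribution
  k <- 2
  ring <- matrix(0, 4, 4)
  for (i in 1:4) {
    j <- i %% 4 + 1
    ring[j, i] <- ring[j, i] + k
    ring[i, j] <- ring[i, j] + k
  }
  diag(ring) <- -colSums(ring)
  dimnames(ring) <- rep(list(c("C_F", "A_F", "D_eg", "SB")), 2)
  expect_equal(unname(solve_kinetics(ring)$stationary), rep(0.25, 4))
})

test_that("detailed balance holds exactly for the reconciled set", {
  r <- derive_rates()
  expect_equal(detailed_balance_residual(r), 1, tolerance = 1e-12)
  # printed 0.89 instead of 80/90 leaves a 0.13% residual
  r2 <- r; r2$k_DS <- 0.89
  expect_equal(detailed_balance_residual(r2), 0.89 / (80 / 90),
               tolerance = 1e-12)
  r3 <- r; r3$k_SD <- 0
  expect_warning(val <- detailed_balance_residual(r3), "infinite")
  expect_identical(val, Inf)
})

test_that("detailed balance implies the pairwise-equilibrium stationary state", {
  r <- derive_rates()
  sol <- solve_kinetics(rate_matrix(r))
  ratios <- c(1, r$k1 / r$km1, (r$k1 / r$km1) * (r$k2 / r$km2),
              (r$k1 / r$km1) * (r$k3 / r$km3))
  expect_equal(unname(sol$stationary), ratios / sum(ratios),
               tolerance = 1e-8)
})

test_that("time propagation conserves probability over 10 decades", {
  sol <- solve_kinetics(rate_matrix(derive_rates()), initial = c(1, 0, 0, 0))
  times <- 10^seq(-8, 2, length.out = 40)
  traj <- propagate_kinetics(sol, times)
  expect_equal(rowSums(traj), rep(1, nrow(traj)), tolerance = 1e-9)
  # long-time limit (past the ~900 s slowest phase) is stationary
  late <- propagate_kinetics(sol, 1e5)
  expect_equal(late[1, ], sol$stationary, tolerance = 1e-6)
})

test_that("eigen amplitudes reconstruct the initial condition", {
  sol <- solve_kinetics(rate_matrix(derive_rates()), initial = c(1, 0, 0, 0))
  expect_equal(unname(rowSums(sol$amplitudes)), c(1, 0, 0, 0),
               tolerance = 1e-9)
  # zero-phase amplitude is the stationary distribution
  expect_equal(unname(sol$amplitudes[, 1]), unname(sol$stationary),
               tolerance = 1e-6)
})

test_that("antenna search time is on the 10 ms scale", {
  sol <- solve_kinetics(rate_matrix(derive_rates()))
  t2 <- sol$times[3]   # intermediate phase
  expect_gt(t2, 0.010)
  expect_lt(t2, 0.012)
})

test_that("copy-number partition splits the cellular pool per gene", {
  sol <- solve_kinetics(rate_matrix(derive_rates()))
  part <- copy_number_partition(sol, 30000, 200)
  expect_equal(part$in_antenna_per_gene + part$elsewhere_per_gene,
               30000 / 200)
  fake <- sol
  fake$stationary <- c(C_F = 1, A_F = 0, D_eg = 0, SB = 0)
  part2 <- copy_number_partition(fake, 1000, 10)
  expect_equal(part2$elsewhere_per_gene, 100)
  expect_equal(part2$in_antenna_per_gene, 0)
  expect_error(copy_number_partition(sol, 1000, 0), "n_genes")
})

test_that("jump-chain simulation agrees with the spectral stationary state", {
  # moderately stiff antenna rate set that mixes within the jump budget
  r <- antenna_rates(k1 = 1, km1 = 20, k2 = 50, km2 = 20, k3 = 5, km3 = 2,
                     k_DS = 4 * (5 * 20) / (2 * 50), k_SD = 4)
  expect_equal(detailed_balance_residual(r), 1, tolerance = 1e-12)
  Q <- rate_matrix(r)
  sol <- solve_kinetics(Q)
  sim <- simulate_jumps(Q, n_jumps = 2e5, seed = 42)
  for (k in 1:4) {
    expect_lt(abs(sim$occupancy[k] - sol$stationary[k]),
              3 * max(sim$se[k], 1e-4))
  }
})

test_that("solver rejects malformed generators", {
  Q <- rate_matrix(derive_rates())
  bad <- Q; bad[1, 1] <- bad[1, 1] + 5
  expect_error(solve_kinetics(bad), "sum to zero")
  bad2 <- Q; bad2[2, 1] <- -1; bad2[1, 1] <- bad2[1, 1] + Q[2, 1] + 1
  expect_error(solve_kinetics(bad2))
})
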