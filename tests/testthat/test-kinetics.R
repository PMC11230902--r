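test_that("network spec wires rates and stoichiometry from s and separation", {
  spec <- network_spec(8)
  expect_equal(spec$kr$k1_S / spec$kr$k1_R, 8)
  expect_equal(spec$L0, spec$A0 / 2)
  expect_equal(spec$coupling$k2_homo, spec$kr$k1_R / 1e3)
  expect_equal(spec$coupling$induction_ratio, 1)
  expect_error(network_spec(0.5), class = "domain_error")
})

test_that("deterministic run to completion reproduces the sequential pipeline", {
  tr <- simulate_deterministic(network_spec(8))
  d <- trajectory_distribution(tr)
  e <- ee_product_at_conversion(8, 0.5)
  expect_equal(hetero_ee(d), coupled_ee(e, e), tolerance = 1e-4)
  expect_equal(round(100 * hetero_ee(d)), 90)
  expect_equal(dr_of(d), coupled_dr(e, e), tolerance = 1e-3)

  # no stereochemical information anywhere at s = 1
  d1 <- trajectory_distribution(simulate_deterministic(network_spec(1)))
  expect_equal(hetero_ee(d1), 0, tolerance = 1e-10)
  expect_equal(dr_of(d1), 1, tolerance = 1e-8)
})

test_that("conservation invariants hold along deterministic trajectories", {
  for (s in c(1, 8, 100)) {
    tr <- simulate_deterministic(network_spec(s))
    res <- conservation_residuals(tr)
    expect_lt(res[["substrate"]], 1e-8)
    expect_lt(res[["linker"]], 1e-8)
    expect_true(all(as.matrix(tr$states) >= 0))
  }
})

test_that("intermediate pool at half-conversion matches the closed form", {
  # the coupling stage consumes substrate at O(1/separation), so agreement
  # with the closed form tightens as the timescales separate
  tr3 <- simulate_deterministic(network_spec(28, separation_factor = 1e3),
                                stop_at_conversion = 0.5)
  ee3 <- ee_of(intermediate_pool(tr3))
  expect_equal(ee3, ee_product_at_conversion(28, 0.5), tolerance = 1e-3)
  tr6 <- simulate_deterministic(network_spec(28, separation_factor = 1e6),
                                stop_at_conversion = 0.5)
  ee6 <- ee_of(intermediate_pool(tr6))
  expect_equal(ee6, ee_product_at_conversion(28, 0.5), tolerance = 1e-4)
  expect_lt(abs(ee6 - ee_product_at_conversion(28, 0.5)),
            abs(ee3 - ee_product_at_conversion(28, 0.5)))
  # interpolated sampling from a continuous run agrees with the solver stop
  tr <- simulate_deterministic(network_spec(28), n_out = 1000)
  st <- state_at_conversion(tr, 0.5)
  expect_equal(ee_from_pool_counts(st[["I_S"]], st[["I_R"]]), ee3,
               tolerance = 1e-5)
})

test_that("breaking the separation or no-induction assumptions moves the outputs", {
  e <- ee_product_at_conversion(8, 0.5)
  seq_ee <- coupled_ee(e, e)
  seq_dr <- coupled_dr(e, e)
  # overlapping timescales
  d_mix <- trajectory_distribution(
    simulate_deterministic(network_spec(8, separation_factor = 1)))
  expect_gt(abs(hetero_ee(d_mix) - seq_ee), 1e-3)
  # asymmetric induction favouring the heterochiral pairing
  d_ind <- trajectory_distribution(
    simulate_deterministic(network_spec(8, induction_ratio = 5)))
  expect_gt(dr_of(d_ind), seq_dr * 1.5)
})

test_that("mirroring the initial state and rate constants mirrors the trajectory", {
  spec <- network_spec(8, ee0 = 0.3)
  y0 <- stereokin:::initial_state(spec)
  k <- stereokin:::rate_params(spec)
  km <- k
  km[c("k1_S", "k1_R")] <- k[c("k1_R", "k1_S")]
  perm <- c(2, 1, 3, 5, 4, 7, 6, 9, 8)  # S <-> R everywhere
  y0m <- y0[perm]
  names(y0m) <- names(y0)
  times <- seq(0, 50, length.out = 60)
  s1 <- deSolve::ode(y0, times, stereokin:::network_rhs, k,
                     method = "lsodar", rtol = 1e-10, atol = 1e-12)
  s2 <- deSolve::ode(y0m, times, stereokin:::network_rhs, km,
                     method = "lsodar", rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(s1[, 1 + perm] - s2[, -1])), 1e-9)
})

test_that("stochastic simulation is seed-deterministic and conserves units", {
  spec <- network_spec(8)
  t1 <- simulate_stochastic(spec, 1e4, seed = 11)
  t2 <- simulate_stochastic(spec, 1e4, seed = 11)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$times, t2$times)
  t3 <- simulate_stochastic(spec, 1e4, seed = 12)
  expect_false(identical(t1$states, t3$states))

  res <- conservation_residuals(t1)   # exact in counts
  expect_equal(unname(res), c(0, 0))

  # an all-S substrate pool can never form R-containing products
  trS <- simulate_stochastic(network_spec(8, ee0 = 1), 1e4, seed = 5)
  expect_true(all(trS$states$P_RS == 0))
  expect_true(all(trS$states$P_RR == 0))
  expect_true(all(trS$states$A_R == 0))

  expect_error(simulate_stochastic(spec, 10, seed = 1), class = "domain_error")
  expect_error(simulate_stochastic(spec, 1e4, seed = "a"), class = "input_error")
})

test_that("stochastic means converge to the deterministic final e.e.", {
  spec <- network_spec(8)
  det <- hetero_ee(trajectory_distribution(simulate_deterministic(spec)))
  ees <- vapply(1:10, function(i) {
    hetero_ee(trajectory_distribution(simulate_stochastic(spec, 2e4, seed = i)))
  }, numeric(1))
  se <- stats::sd(ees) / sqrt(length(ees))
  expect_lt(abs(mean(ees) - det), 4 * se + 1e-4)
})

test_that("selectivity sweep is monotone and hits the printed anchors", {
  tab <- sweep_selectivity(c(1, 2, 8, 28, 100))
  expect_equal(tab$ee_intermediate_50[tab$s == 1], 0)
  expect_equal(tab$ee_final[tab$s == 1], 0)
  expect_equal(tab$dr_final[tab$s == 1], 1)
  expect_equal(round(100 * tab$ee_intermediate_50[tab$s == 8]), 62)
  expect_equal(round(100 * tab$ee_final[tab$s == 8]), 90)
  expect_equal(round(tab$dr_final[tab$s == 8], 1), 2.3)
  expect_equal(round(100 * tab$ee_intermediate_50[tab$s == 28]), 83)
  expect_true(all(diff(tab$ee_intermediate_50) > 0))
  expect_true(all(diff(tab$ee_final) > 0))
  expect_true(all(diff(tab$dr_final) > 0))
  expect_error(sweep_selectivity(c(2, 0.5)), class = "domain_error")
  expect_error(sweep_selectivity(numeric(0)), class = "input_error")
})
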