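test_that("statistical coupling matches brute-force pairing enumeration", {
  # 96% and 99% e.e. pools as integer molecule counts (oracle: direct
  # enumeration of all ordered pairs)
  oracle <- brute_force_coupling(nS1 = 980, nR1 = 20, nS2 = 5, nR2 = 995)
  d <- statistical_coupling(pool_from_ee(0.96, 1000, "intermediate"),
                            pool_from_ee(-0.99, 1000, "substrate"))
  expect_equal(c(d$hetero_SR, d$hetero_RS, d$homo_SS, d$homo_RR),
               oracle, tolerance = 1e-12)
  expect_equal(hetero_ee(d), 0.9997949, tolerance = 1e-6)
  expect_equal(dr_of(d), 39.32258, tolerance = 1e-5)
  # closed forms against the distribution route
  expect_equal(hetero_ee(d), coupled_ee(0.96, 0.99), tolerance = 1e-12)
  expect_equal(dr_of(d), coupled_dr(0.96, 0.99), tolerance = 1e-12)
})

test_that("coupling both pools at the s = 8 resolution e.e. amplifies to ~90%", {
  e <- ee_product_at_conversion(8, 0.5)
  d <- statistical_coupling(pool_from_ee(e, 1, "intermediate"),
                            pool_from_ee(-e, 1, "substrate"))
  expect_equal(hetero_ee(d), coupled_ee(e, e), tolerance = 1e-12)
  expect_equal(round(100 * hetero_ee(d)), 90)
  # racemic pools give the statistical 1:1 mixture
  d0 <- statistical_coupling(pool_from_ee(0, 1), pool_from_ee(0, 1))
  expect_equal(hetero_ee(d0), 0)
  expect_equal(dr_of(d0), 1)
  expect_error(statistical_coupling(enantiomer_pool(0, 0), pool_from_ee(0.5, 1)),
               class = "undefined_quantity_error")
})

test_that("statistical coupling conserves S and R units from both pools", {
  set.seed(33)
  for (i in 1:25) {
    p1 <- enantiomer_pool(runif(1, 0, 2), runif(1, 0, 2))
    p2 <- enantiomer_pool(runif(1, 0, 2), runif(1, 0, 2))
    n <- min(pool_total(p1), pool_total(p2))
    d <- statistical_coupling(p1, p2)
    # S units drawn: pool1 contributes f1S*n, pool2 f2S*n
    expect_equal(d$hetero_SR + d$homo_SS,
                 n * p1$amount_S / pool_total(p1), tolerance = 1e-12)
    expect_equal(d$hetero_RS + d$homo_SS,
                 n * p2$amount_S / pool_total(p2), tolerance = 1e-12)
    expect_equal(d$hetero_RS + d$homo_RR,
                 n * p1$amount_R / pool_total(p1), tolerance = 1e-12)
    expect_equal(d$hetero_SR + d$homo_RR,
                 n * p2$amount_R / pool_total(p2), tolerance = 1e-12)
  }
})

test_that("Horeau homocoupling amplifies and agrees with self-coupling", {
  d <- horeau_homocoupling(pool_from_ee(0.62, 1))
  expect_equal(homochiral_ee(d), 0.8956949, tolerance = 1e-6)
  expect_equal(meso_fraction(d), 0.3078, tolerance = 1e-4)
  expect_equal(homochiral_ee(horeau_homocoupling(pool_from_ee(1, 1))), 1)
  expect_equal(meso_fraction(horeau_homocoupling(pool_from_ee(1, 1))), 0)
  expect_equal(homochiral_ee(horeau_homocoupling(pool_from_ee(0, 1))), 0)
  expect_equal(meso_fraction(horeau_homocoupling(pool_from_ee(0, 1))), 0.5)

  # amplification identity 2e/(1+e^2) >= e, equality only at 0 and 1
  for (e in seq(0, 1, by = 0.05)) {
    amp <- 2 * e / (1 + e^2)
    dd <- horeau_homocoupling(pool_from_ee(e, 1))
    expect_equal(homochiral_ee(dd), amp, tolerance = 1e-12)
    if (e %in% c(0, 1)) expect_equal(amp, e) else expect_gt(amp, e)
  }

  # homocoupling == statistical coupling with a mirrored copy, with the
  # hetero and homo roles swapped
  p <- pool_from_ee(0.37, 2)
  hc <- horeau_homocoupling(p)
  m <- statistical_coupling(p, mirror_pool(p))
  # against the mirrored partner the roles swap exactly
  expect_equal(m$hetero_SR + m$hetero_RS, 2 * (hc$homo_SS + hc$homo_RR),
               tolerance = 1e-12)
  expect_equal(m$homo_SS + m$homo_RR, 2 * (hc$hetero_SR + hc$hetero_RS),
               tolerance = 1e-12)
})

test_that("infer_pool_ees inverts statistical coupling and flags infeasibility", {
  inf <- infer_pool_ees(39.3, 0.9998)
  expect_true(inf$feasible)
  expect_equal(inf$a, 0.99, tolerance = 2e-3)
  expect_equal(inf$b, 0.96, tolerance = 2e-3)

  # round trip over a grid of pool pairs
  for (a in seq(0.05, 0.99, length.out = 8)) for (b in seq(0, 0.95, length.out = 8)) {
    r <- infer_pool_ees(coupled_dr(a, b), coupled_ee(a, b))
    expect_true(r$feasible)
    expect_equal(sort(c(r$a, r$b)), sort(c(a, b)), tolerance = 1e-9)
  }

  expect_false(infer_pool_ees(3.2, 0.93)$feasible)
  expect_false(infer_pool_ees(1.4, 0.66)$feasible)
  expect_match(infer_pool_ees(3.2, 0.93)$reason, "no statistical")
  r0 <- infer_pool_ees(1, 0)
  expect_true(r0$feasible)
  expect_equal(c(r0$a, r0$b), c(0, 0))
  expect_error(infer_pool_ees(0.8, 0.5), class = "domain_error")
})

test_that("coupling parameters carry the induction ratio", {
  cp <- coupling_parameters(2e-3, 1e-3)
  expect_equal(cp$induction_ratio, 2)
  expect_equal(coupling_parameters(5e-4)$induction_ratio, 1)
  expect_error(coupling_parameters(0), class = "domain_error")
})
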