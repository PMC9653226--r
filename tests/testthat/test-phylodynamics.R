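test_that("Yule density matches the hand-derived closed form", {
  # delta = 0, rho = 1, no conditioning: the oriented-tree density is
  # lambda^(n-1) * exp(-lambda * L) with L = origin branch + all branch
  # lengths (each lineage persists until it branches or is sampled)
  lam <- 0.2
  tr3 <- parse_newick("((A:4,B:4):6,C:10):2;", origin_height = 12)
  L <- 12 + sum(scartree:::internal_ages(tr3))
  expect_equal(bds_log_density(tr3, bds_params(lam, 0, 1, 12),
                               condition = "none"),
               2 * log(lam) - lam * L, tolerance = 1e-12)
  # a different 3-tip labelled history with the same branching times has
  # the same density (exchangeability over tip labels)
  tr3b <- parse_newick("((C:4,A:4):6,B:10):2;", origin_height = 12)
  expect_equal(bds_log_density(tr3b, bds_params(lam, 0, 1, 12)),
               bds_log_density(tr3, bds_params(lam, 0, 1, 12)))
  # survival conditioning only shifts by log P(N >= 1) (= 0 for rho = 1,
  # delta = 0: a Yule tree always survives)
  expect_equal(bds_log_density(tr3, bds_params(lam, 0, 1, 12), "survival"),
               bds_log_density(tr3, bds_params(lam, 0, 1, 12), "none"))
  expect_error(bds_log_density(tr3, bds_params(lam, 0, 1, 10)), "origin_time")
})

test_that("2-tip density integrates to the Monte Carlo tip-count probability", {
  set.seed(61)
  lam <- 0.25; del <- 0.1; rho <- 0.5; t_or <- 6
  f <- Vectorize(function(x)
    exp(scartree:::bds_log_density_ages(x, lam, del, rho, t_or)))
  p2_analytic <- stats::integrate(f, 0, t_or)$value
  sims <- replicate(30000, simulate_tree(bds_params(lam, del, rho, t_or),
                                         max_cells = 5000)$n_sampled)
  surv <- sims[sims > 0]
  p2_mc <- mean(surv == 2)
  se <- sqrt(p2_mc * (1 - p2_mc) / length(surv))
  expect_lt(abs(p2_analytic - p2_mc), 3 * se + 1e-9)
})

test_that("tip-count law is geometric and the range mass is exact", {
  set.seed(67)
  lam <- 0.14; del <- 0.05; rho <- 0.4; t <- 20
  sims <- replicate(30000, simulate_tree(bds_params(lam, del, rho, t),
                                         max_cells = 5000)$n_sampled)
  for (rg in list(c(1, 1), c(2, 5), c(3, 15))) {
    p_mc <- mean(sims >= rg[1] & sims <= rg[2])
    p_cf <- bds_tip_range_prob(rg[1], rg[2], lam, del, rho, t)
    expect_lt(abs(p_mc - p_cf), 3 * sqrt(p_cf * (1 - p_cf) / length(sims)) + 1e-9)
  }
  # whole support sums to one
  expect_equal(bds_tip_range_prob(0, Inf, lam, del, rho, t), 1,
               tolerance = 1e-12)
})

test_that("expected tip count has its closed form and matches simulation", {
  expect_equal(expected_tip_count(bds_params(0.1, 0.1, 0.3, 10)), 0.3)
  expect_equal(expected_tip_count(bds_params(0.1, 0, 1, 32)), exp(3.2))
  set.seed(71)
  p <- bds_params(0.12, 0.04, 0.6, 20)
  ns <- replicate(4000, simulate_tree(p, max_cells = 5000)$n_sampled)
  se <- sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - expected_tip_count(p)), 3 * se)
})

test_that("profile in rho is flat relative to lambda on a single tree", {
  # the known identifiability limit: from one alignment's tree, the
  # sampling proportion is barely informed while the birth rate is
  set.seed(73)
  sim <- simulate_dataset(bds_params(0.15, 0, 0.4, 32),
                          demo_model(t1 = 0, t2 = 16), n_targets = 5,
                          min_tips = 10, max_tips = 60, seed = 3)
  tr <- sim$tree
  # matched +/- 50% grids around the truth for a fair comparison
  prof_rho <- vapply(seq(0.2, 0.6, length.out = 19), function(rho)
    bds_log_density(tr, bds_params(0.15, 0, rho, 32)), numeric(1))
  prof_lam <- vapply(seq(0.075, 0.225, length.out = 19), function(lam)
    bds_log_density(tr, bds_params(lam, 0, 0.4, 32)), numeric(1))
  expect_lt(diff(range(prof_rho)), diff(range(prof_lam)) / 3)
})
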