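test_that("tree simulation is deterministic and respects the sampling law", {
  p <- bds_params(0.2, 0.05, 0.6, 12)
  s1 <- simulate_tree(p, seed = 10)
  s2 <- simulate_tree(p, seed = 10)
  expect_identical(write_newick(s1$sampled), write_newick(s2$sampled))
  expect_false(identical(write_newick(s1$sampled),
                         write_newick(simulate_tree(p, seed = 11)$sampled)))
  # sampled tree is a valid timetree; full tree retains extinct lineages
  expect_s3_class(s1$sampled, "timetree")
  expect_gte(length(s1$full$parent), length(s1$sampled$parent))
})

test_that("Yule tip counts follow the geometric law", {
  set.seed(79)
  lam <- 0.3; t <- 5
  ns <- replicate(10000, simulate_tree(bds_params(lam, 0, 1, t))$n_sampled)
  # pure birth from one lineage: N ~ Geometric with success prob exp(-lam t)
  q <- exp(-lam * t)
  obs <- table(factor(pmin(ns, 15), levels = 1:15))
  expp <- q * (1 - q)^(0:13)
  expp <- c(expp, 1 - sum(expp))
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs), p = expp))
  expect_gt(gof$p.value, 0.001)
  se <- sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - exp(lam * t)), 3 * se)
})

test_that("barcode simulation matches the editing closed forms", {
  set.seed(83)
  # near-star tree: each tip lineage is almost a single lineage over [0, t_s]
  tr <- parse_newick("(A:31.9,B:31.9):0.1;", origin_height = 32)
  mod <- editing_model(0.05, c(3, 1), window_start = 0, window_end = 16)
  tab <- simulate_barcodes(tr, mod, n_targets = 12000, seed = 5)
  st <- edit_table_states(tab)["A", ]
  p_unedited <- exp(-0.05 * 4 * 16)
  ci <- 3 * sqrt(p_unedited * (1 - p_unedited) / length(st))
  expect_lt(abs(mean(st == 0) - p_unedited), ci + 0.02 * p_unedited)
  # scar outcomes among edited integrations in ratio s_i / sigma
  sc <- st[st >= 2]
  expect_lt(abs(mean(sc == 2) - 0.75), 3 * sqrt(0.75 * 0.25 / length(sc)))
  # r = 0: everything stays unedited
  tab0 <- simulate_barcodes(tr, editing_model(0, c(1, 1), window_start = 0,
                                              window_end = 16),
                            n_targets = 50, seed = 1)
  expect_true(all(edit_table_states(tab0) == 0L))
})

test_that("dropout masks observations at the configured rate", {
  set.seed(89)
  tr <- random_timetree(8, t_s = 12)
  tab <- simulate_barcodes(tr, demo_model(), n_targets = 500,
                           dropout_prob = 0.25)
  frac <- mean(is.na(edit_table_states(tab)))
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / (8 * 500)))
})

test_that("datasets feed the likelihood finitely and retention is honoured", {
  set.seed(97)
  mod <- editing_model(0.05, c(3, 1), window_start = 0, window_end = 16)
  for (i in 1:5) {
    ds <- simulate_dataset(bds_params(0.12, 0.02, 0.5, 32), mod,
                           n_targets = 10, min_tips = 4, max_tips = 30)
    expect_true(n_tips(ds$tree) >= 4 && n_tips(ds$tree) <= 30)
    expect_true(is.finite(tree_log_likelihood(ds$tree, ds$table, mod)))
  }
})

test_that("calibrated study draws truths from the priors", {
  set.seed(101)
  pr <- prior_spec(r = prior_lognormal(log(0.05), 0.5),
                   lambda = prior_lognormal(log(0.08), 0.25),
                   rho = prior_uniform(0.1, 0.9),
                   s = prior_fixed(2))
  st <- run_calibrated_study(pr, 60, template = list(n_targets = 4,
                                                     min_tips = 2),
                             seed = 7)
  expect_equal(nrow(st$truths), 60)
  expect_equal(length(unique(st$truths$seed)), 60)
  # marginals match the priors they were drawn from (the retention policy
  # only filters datasets, not the recorded truths... truths are drawn
  # before simulation, so r is untouched by retention)
  ks <- ks.test(st$truths$r, scartree:::prior_cdf_fun(prior_lognormal(log(0.05), 0.5)))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(st$truths$s_1 == 2))
  expect_true(all(st$truths$n_tips >= 2))
})
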