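test_that("edit tables read, write and validate", {
  tab <- edit_table(matrix(c(0L, 2L, NA, 3L, 1L, 0L), 2, 3),
                    cells = c("A", "B"))
  f <- tempfile(fileext = ".tsv")
  write_edit_table(tab, f)
  rt <- read_edit_table(f)
  expect_equal(as.data.frame(rt), as.data.frame(tab))
  fcsv <- tempfile(fileext = ".csv")
  write_edit_table(tab, fcsv)
  expect_equal(as.data.frame(read_edit_table(fcsv)), as.data.frame(tab))
  expect_error(edit_table(matrix(0, 2, 2), cells = c("A", "A")), "unique")
  expect_error(edit_table(matrix(-1, 1, 1)), "non-negative")
  # silenced-as-missing remap
  st <- edit_table_states(tab, silenced_is_missing = TRUE)
  expect_true(is.na(st["A", 3]))
})

test_that("single shared lineage likelihood has the survival closed form", {
  # both tips unedited, l = 0: only the editing window can act, and both
  # lineages traverse it on the shared path => exp(-r * sigma * (t2 - t1))
  mod <- editing_model(0.1, c(1, 1), window_start = 0, window_end = 5)
  tr <- parse_newick("(A:1,B:1):11;", origin_height = 12)
  tab <- edit_table(matrix(c(0L, 0L), 2, 1), cells = c("A", "B"))
  expect_equal(tree_log_likelihood(tr, tab, mod), -0.1 * 2 * 5,
               tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on 3- and 4-tip topologies", {
  set.seed(17)
  mod <- editing_model(0.08, c(2, 1), silencing_rate = 0.02,
                       window_start = 3, window_end = 9)
  shapes <- list(
    "((A:%f,B:%f):%f,C:%f):%f;",         # 3-tip
    "((A:%f,B:%f):%f,(C:%f,D:%f):%f):%f;", # balanced 4-tip
    "(((A:%f,B:%f):%f,C:%f):%f,D:%f):%f;") # caterpillar 4-tip
  worst <- 0
  for (rep in 1:6) {
    for (si in seq_along(shapes)) {
      # random ultrametric node times over [0, 12]
      tr <- random_timetree(if (si == 1) 3 else 4, t_s = 12)
      tab <- simulate_barcodes(tr, mod, n_targets = 3)
      bf <- brute_force_loglik(tr, tab, mod)
      pr <- tree_log_likelihood(tr, tab, mod)
      worst <- max(worst, abs(bf - pr))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("per-site terms factorize, permute and sum to the total", {
  set.seed(23)
  mod <- demo_model()
  tr <- random_timetree(6, t_s = 12)
  tab <- simulate_barcodes(tr, mod, n_targets = 5)
  per <- per_site_log_likelihoods(tr, tab, mod)
  expect_equal(sum(per), tree_log_likelihood(tr, tab, mod), tolerance = 1e-12)
  # permuting columns permutes elements
  perm <- sample(5)
  tab2 <- tab[, c(1, perm + 1)]
  class(tab2) <- class(tab)
  expect_equal(per_site_log_likelihoods(tr, tab2, mod), per[perm])
  # identical columns under a shared model give identical elements
  tab3 <- tab
  for (j in 3:6) tab3[[j]] <- tab3[[2]]
  per3 <- per_site_log_likelihoods(tr, tab3, mod)
  expect_true(max(per3) - min(per3) < 1e-12)
  # adding targets adds their terms
  expect_equal(tree_log_likelihood(tr, tab, mod),
               sum(vapply(2:6, function(j) {
                 one <- tab[, c(1, j)]
                 class(one) <- class(tab)
                 tree_log_likelihood(tr, one, editing_model(
                   mod$edit_rate, mod$scarring_multipliers,
                   mod$silencing_rate, mod$window_start, mod$window_end))
               }, numeric(1))), tolerance = 1e-12)
})

test_that("likelihood is invariant to subdivision and label permutation", {
  set.seed(29)
  for (i in 1:8) {
    mod <- random_model()
    tr <- random_timetree(sample(4:8, 1), t_s = 12)
    tab <- simulate_barcodes(tr, mod, n_targets = 4)
    base <- tree_log_likelihood(tr, tab, mod)
    # inserting extra degree-2 nodes anywhere does not change it
    cuts <- sort(runif(2, 1, 11))
    sub <- subdivide_at_window(tr, cuts[1], cuts[2])
    expect_equal(tree_log_likelihood(sub, tab, mod), base, tolerance = 1e-10)
    # permuting cells together with rows leaves it unchanged
    tab_shuffled <- tab[sample(nrow(tab)), ]
    class(tab_shuffled) <- class(tab)
    expect_equal(tree_log_likelihood(tr, tab_shuffled, mod), base,
                 tolerance = 1e-12)
  }
})

test_that("impossible scar configurations are reported with a diagnostic", {
  # scarred tips under a cherry that diverged after the window cannot carry
  # different scars
  mod <- editing_model(0.1, c(1, 1), window_start = 0, window_end = 4)
  tr <- parse_newick("(A:2,B:2):10;", origin_height = 12)  # MRCA at 10 > t2
  tab <- edit_table(matrix(c(2L, 3L), 2, 1), cells = c("A", "B"))
  expect_error(tree_log_likelihood(tr, tab, mod), "zero likelihood")
  expect_identical(tree_log_likelihood(tr, tab, mod,
                                       on_impossible = "neg_inf"), -Inf)
  # same scar on both tips is fine (acquired on the shared path)
  tab_ok <- edit_table(matrix(c(2L, 2L), 2, 1), cells = c("A", "B"))
  expect_true(is.finite(tree_log_likelihood(tr, tab_ok, mod)))
})

test_that("missing data and site-specific models are handled", {
  set.seed(41)
  mod <- demo_model()
  tr <- random_timetree(5, t_s = 12)
  tab <- simulate_barcodes(tr, mod, n_targets = 4, dropout_prob = 0.3)
  expect_true(is.finite(tree_log_likelihood(tr, tab, mod)))
  # an all-missing column contributes exactly zero log-likelihood
  tab_na <- tab; tab_na[[2]] <- NA_integer_
  class(tab_na) <- class(tab)
  per <- per_site_log_likelihoods(tr, tab_na, mod)
  expect_equal(per[1], 0)
  # free per-site models agree with per-column evaluation
  mods <- lapply(c(0.05, 0.1, 0.2, 0.3), function(r)
    editing_model(r, c(2, 1), silencing_rate = 0.01,
                  window_start = 3, window_end = 9))
  sm <- site_models(mods, sharing = "free")
  per_free <- per_site_log_likelihoods(tr, tab, sm)
  for (j in 1:4) {
    one <- tab[, c(1, j + 1)]
    class(one) <- class(tab)
    expect_equal(per_free[j], tree_log_likelihood(tr, one, mods[[j]]),
                 tolerance = 1e-12)
  }
  # label mismatch and out-of-range states are input errors
  bad <- tab; bad$cell[1] <- "nope"
  class(bad) <- class(tab)
  expect_error(tree_log_likelihood(tr, bad, mod), "one-to-one")
  bad2 <- tab; bad2[[2]][1] <- 9L
  class(bad2) <- class(tab)
  expect_error(tree_log_likelihood(tr, bad2, mod), "out of range")
})

test_that("deep tables do not underflow and l = 0 profiles peak near truth", {
  set.seed(53)
  mod <- editing_model(0.06, c(3, 1), window_start = 0, window_end = 16)
  sim <- simulate_dataset(bds_params(0.18, 0, 0.9, 32), mod, n_targets = 40,
                          min_tips = 120, max_tips = 400, seed = 2)
  ll <- tree_log_likelihood(sim$tree, sim$table, mod)
  expect_true(is.finite(ll))
  # profile in r on the true tree is maximized near the simulated truth
  rs <- seq(0.02, 0.12, by = 0.005)
  prof <- vapply(rs, function(r)
    tree_log_likelihood(sim$tree, sim$table,
                        editing_model(r, c(3, 1), window_start = 0,
                                      window_end = 16)), numeric(1))
  r_hat <- rs[which.max(prof)]
  # Fisher-information-scale tolerance at this problem size
  expect_lt(abs(r_hat - 0.06), 0.015)
})
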