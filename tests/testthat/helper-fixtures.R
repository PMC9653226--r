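# Shared fixtures built in code.

# small editing model with uneven scar multipliers
demo_model <- function(r = 0.08, s = c(2, 1), l = 0.03, t1 = 3, t2 = 9) {
  editing_model(edit_rate = r, scarring_multipliers = s, silencing_rate = l,
                window_start = t1, window_end = t2)
}

# a fixed 4-tip tree over [0, 12]
demo_tree <- function(t_s = 12) {
  parse_newick("((A:2,B:2):9,(C:6,D:6):5):1;", origin_height = t_s)
}

# random editing model draw for property tests
random_model <- function() {
  S <- sample(1:3, 1)
  editing_model(edit_rate = runif(1, 0, 0.4),
                scarring_multipliers = c(runif(S - 1, 0.1, 4), 1)[seq_len(S)],
                silencing_rate = runif(1, 0, 0.1),
                window_start = runif(1, 0, 5),
                window_end = runif(1, 5, 12))
}

# random coalescent-ish timetree on n tips over [0, t_s] (labels cell_i)
random_timetree <- function(n, t_s = 12) {
  sim <- NULL
  while (is.null(sim) || sim$n_sampled != n) {
    sim <- simulate_tree(bds_params(0.25, 0, 0.8, t_s), max_cells = 5000)
  }
  sim$sampled
}

# brute-force enumeration of the tree likelihood: subdivides at the window,
# enumerates every non-tip node state, multiplies per-branch closed-form
# transition probabilities (independent of the pruning code path)
brute_force_loglik <- function(tree, table, model) {
  trs <- subdivide_at_window(tree, model$window_start, model$window_end)
  kids <- scartree:::tree_children(trs)
  tips <- scartree:::tree_tips(trs)
  states <- scartree:::align_table_to_tips(table, trs$label[tips])
  k <- model$scar_count + 2L
  nodes <- seq_along(trs$parent)
  free <- setdiff(nodes, tips)
  origin <- scartree:::tree_origin(trs)
  # per-branch transition matrices
  P <- vector("list", length(nodes))
  for (nd in nodes) {
    p <- trs$parent[nd]
    if (!is.na(p))
      P[[nd]] <- transition_probabilities(model, trs$time[p], trs$time[nd])
  }
  # enumerate every assignment of states to the free (non-tip) nodes,
  # vectorized over the assignment grid
  grid <- as.matrix(expand.grid(rep(list(0:(k - 1)), length(free))))
  grid <- grid[grid[, match(origin, free)] == 0L, , drop = FALSE]  # origin unedited
  full <- matrix(0L, nrow(grid), length(nodes))
  full[, free] <- grid
  total <- 0
  for (j in seq_len(ncol(states))) {
    full[, tips] <- matrix(states[, j], nrow(grid), length(tips), byrow = TRUE)
    pr <- rep(1, nrow(grid))
    for (nd in nodes) {
      p <- trs$parent[nd]
      if (is.na(p)) next
      pr <- pr * P[[nd]][cbind(full[, p] + 1L, full[, nd] + 1L)]
    }
    total <- total + log(sum(pr))
  }
  total
}

# number of free (enumerated) nodes after window subdivision; used to skip
# trees whose enumeration grid would be too large for the oracle
brute_force_grid_size <- function(tree, model) {
  trs <- subdivide_at_window(tree, model$window_start, model$window_end)
  length(trs$parent) - length(scartree:::tree_tips(trs))
}
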