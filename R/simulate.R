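#' Simulate a birth-death tree with sampling at the experiment end
#'
#' Gillespie simulation of the cell population forward in time from a single
#' precursor cell at the origin (time 0): each cell divides at rate lambda
#' and dies at rate delta; at the sampling time each extant cell is retained
#' independently with probability rho. The sampled tree is the tree induced
#' on the retained cells with extinct and unsampled lineages pruned and
#' pass-through nodes suppressed, keeping the degree-1 origin on top.
#'
#' @param params A \code{\link{bds_params}}; \code{origin_time} is the
#'   sampling time t_s.
#' @param seed Optional integer seed for reproducibility.
#' @param max_cells Abort guard on the extant population size.
#' @return A list with \code{sampled} (a validated \code{timetree}, or NULL
#'   if no cell was sampled), \code{full} (the complete developmental tree,
#'   including extinct lineages, as an unvalidated \code{timetree}),
#'   \code{n_sampled} and \code{n_extant}.
#' @export
simulate_tree <- function(params, seed = NULL, max_cells = 100000) {
  stopifnot(inherits(params, "bds_params"))
  if (!is.null(seed)) set.seed(seed)
  t_s <- params$origin_time
  lambda <- params$birth_rate; delta <- params$death_rate
  # growing node arrays: node 1 = origin, node 2 = first cell
  parent <- c(NA_integer_, 1L)
  time <- c(0, NA_real_)        # time filled when the lineage terminates
  birth <- c(0, 0)              # birth time of the lineage
  active <- 2L                  # extant lineage node ids
  now <- 0
  while (length(active) > 0) {
    n_act <- length(active)
    if (n_act > max_cells) stop("population exceeded max_cells", call. = FALSE)
    total <- n_act * (lambda + delta)
    wait <- if (total > 0) rexp(1, total) else Inf
    if (now + wait >= t_s) break
    now <- now + wait
    who <- active[sample.int(n_act, 1L)]
    if (runif(1) < lambda / (lambda + delta)) {     # division
      time[who] <- now
      id <- length(parent) + c(1L, 2L)
      parent[id] <- who
      time[id] <- NA_real_
      birth[id] <- now
      active <- c(active[active != who], id)
    } else {                                        # death
      time[who] <- now
      active <- active[active != who]
    }
  }
  time[active] <- t_s
  n_extant <- length(active)
  keep <- active[runif(n_extant) < params$sampling_proportion]
  label <- rep(NA_character_, length(parent))
  label[keep] <- paste0("cell_", seq_along(keep))
  full <- structure(list(parent = parent, time = time, label = label,
                         t_s = t_s), class = "timetree")
  sampled <- if (length(keep) > 0) prune_to_tips(full, keep) else NULL
  list(sampled = sampled, full = full,
       n_sampled = length(keep), n_extant = n_extant)
}

# Induced tree on the given tip nodes: drop all other lineages, suppress
# pass-through internal nodes, keep a degree-1 origin above the MRCA.
prune_to_tips <- function(tree, tip_nodes) {
  nn <- length(tree$parent)
  n_desc <- integer(nn)
  n_desc[tip_nodes] <- 1L
  for (nd in order(tree$time, decreasing = TRUE)) {
    p <- tree$parent[nd]
    if (!is.na(p)) n_desc[p] <- n_desc[p] + n_desc[nd]
  }
  keep_tip <- seq_len(nn) %in% tip_nodes
  # a node survives if it is a retained tip, the origin, or separates
  # two retained lineages
  kids_kept <- integer(nn)
  for (nd in seq_len(nn)) {
    p <- tree$parent[nd]
    if (!is.na(p) && n_desc[nd] > 0) kids_kept[p] <- kids_kept[p] + 1L
  }
  survive <- keep_tip | is.na(tree$parent) | (kids_kept >= 2L & n_desc > 0)
  # new parent: nearest surviving ancestor
  idx <- which(survive)
  new_id <- integer(nn); new_id[idx] <- seq_along(idx)
  np <- integer(length(idx)); nt <- tree$time[idx]; nl <- tree$label[idx]
  for (j in seq_along(idx)) {
    p <- tree$parent[idx[j]]
    while (!is.na(p) && !survive[p]) p <- tree$parent[p]
    np[j] <- if (is.na(p)) NA_integer_ else new_id[p]
  }
  new_timetree(np, nt, nl, tree$t_s)
}

#' Simulate barcode evolution down a time-scaled tree
#'
#' Each of the m targets evolves independently from the unedited origin state
#' down the tree: along every branch the child state is drawn from the
#' closed-form transition matrix of its editing model across the branch
#' interval (split internally at the scarring-window boundaries). Optional
#' dropout masks each tip observation independently.
#'
#' @param tree A \code{timetree}.
#' @param model An \code{editing_model} plus \code{n_targets}, or a
#'   \code{\link{site_models}}.
#' @param n_targets Number of targets m when \code{model} is a single model.
#' @param dropout_prob Per-integration probability that a tip observation is
#'   missing (applied after simulation, independently per integration).
#' @param seed Optional integer seed.
#' @return An \code{\link{edit_table}} for the tree's tips.
#' @export
simulate_barcodes <- function(tree, model, n_targets = NULL,
                              dropout_prob = 0, seed = NULL) {
  stopifnot(inherits(tree, "timetree"))
  if (!is.null(seed)) set.seed(seed)
  sm <- if (inherits(model, "site_models")) model
        else site_models(model, n_sites = n_targets, sharing = "shared_all")
  m <- sm$n_sites
  grp <- model_groups(sm)
  S <- sm$models[[1]]$scar_count
  k <- S + 2L
  t1 <- sm$models[[1]]$window_start; t2 <- sm$models[[1]]$window_end
  nn <- n_nodes(tree)
  states <- matrix(0L, nn, m)     # origin starts unedited (state 0)
  ord <- order(tree$time)         # preorder: parents before children
  for (nd in ord) {
    p <- tree$parent[nd]
    if (is.na(p)) next
    for (g in seq_along(grp$r)) {
      cols <- which(grp$group0 == g - 1L)
      P <- branch_matrix_cpp(tree$time[p], tree$time[nd], t1, t2,
                             grp$r[g], grp$smat[, g], grp$l[g])
      ps <- states[p, cols]
      for (s_from in unique(ps)) {
        sel <- cols[ps == s_from]
        states[nd, sel] <- sample.int(k, length(sel), replace = TRUE,
                                      prob = P[s_from + 1L, ]) - 1L
      }
    }
  }
  tips <- tree_tips(tree)
  mat <- states[tips, , drop = FALSE]
  if (dropout_prob > 0)
    mat[matrix(runif(length(mat)) < dropout_prob, nrow(mat))] <- NA_integer_
  rownames(mat) <- tree$label[tips]
  colnames(mat) <- paste0("target_", seq_len(m))
  edit_table(mat)
}

#' Simulate one complete lineage-tracing dataset
#'
#' Couples \code{\link{simulate_tree}} and \code{\link{simulate_barcodes}}
#' with a retention policy: replicates whose sampled tree is empty or whose
#' tip count falls outside \code{[min_tips, max_tips]} are resimulated with
#' the next sub-seed (the number of attempts is recorded).
#'
#' @param bds A \code{\link{bds_params}}.
#' @param model \code{editing_model} or \code{site_models}.
#' @param n_targets Targets m (for a single model).
#' @param dropout_prob Per-integration dropout probability.
#' @param min_tips,max_tips Retention bounds on the sampled tip count.
#' @param seed Integer seed (sub-seeds derived by increment).
#' @param max_attempts Resimulation cap.
#' @return A list: \code{tree} (sampled \code{timetree}), \code{full_tree},
#'   \code{table} (\code{edit_table}), \code{n_extant}, \code{attempts},
#'   \code{seed}.
#' @export
simulate_dataset <- function(bds, model, n_targets = NULL, dropout_prob = 0,
                             min_tips = 2, max_tips = Inf, seed = NULL,
                             max_attempts = 1000) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  for (attempt in seq_len(max_attempts)) {
    sub_seed <- (seed + attempt - 1L) %% .Machine$integer.max
    sim <- simulate_tree(bds, seed = sub_seed)
    if (sim$n_sampled >= min_tips && sim$n_sampled <= max_tips) {
      tab <- simulate_barcodes(sim$sampled, model, n_targets = n_targets,
                               dropout_prob = dropout_prob)
      return(list(tree = sim$sampled, full_tree = sim$full, table = tab,
                  n_extant = sim$n_extant, attempts = attempt, seed = sub_seed))
    }
  }
  stop("no replicate satisfied the tip-count retention bounds", call. = FALSE)
}

#' Draw truths from priors and simulate a calibrated study
#'
#' For each replicate, simulation parameters are drawn from the given priors
#' (the same priors later handed to the inference), a dataset is simulated
#' under them, and the (truth, dataset) pair is returned. This is the input
#' to well-calibrated validation: when inference is correct, nominal 95%
#' credible intervals cover the truth for 95% of replicates.
#'
#' @param priors A \code{\link{prior_spec}}; fixed parameters keep their
#'   fixed value as truth.
#' @param n_replicates Number of replicates.
#' @param template Named list of fixed study conditions: \code{S},
#'   \code{window_start}, \code{window_end}, \code{t_s}, \code{n_targets},
#'   \code{dropout_prob}, \code{min_tips}, \code{max_tips}.
#' @param seed Integer seed.
#' @return A list with \code{truths} (tibble, one row per replicate,
#'   including the realized \code{n_tips}, \code{mrca_time},
#'   \code{tree_height}, \code{tree_length}) and \code{datasets} (list of
#'   \code{simulate_dataset} results).
#' @export
run_calibrated_study <- function(priors, n_replicates, template, seed = NULL) {
  stopifnot(inherits(priors, "prior_spec"))
  if (!is.null(seed)) set.seed(seed)
  tpl <- utils::modifyList(list(S = 2, window_start = 0, window_end = 16,
                                t_s = 32, n_targets = 20, dropout_prob = 0,
                                min_tips = 2, max_tips = Inf), template)
  datasets <- vector("list", n_replicates)
  rows <- vector("list", n_replicates)
  rep_seeds <- sample.int(2^30, n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(rep_seeds[i])
    th <- sample_prior_point(priors, S = tpl$S)
    model <- editing_model(edit_rate = th[["r"]],
                           scarring_multipliers = multipliers_from_params(th, tpl$S),
                           silencing_rate = th[["l"]],
                           window_start = tpl$window_start,
                           window_end = tpl$window_end)
    bds <- bds_params(th[["lambda"]], th[["delta"]], th[["rho"]], tpl$t_s)
    ds <- simulate_dataset(bds, model, n_targets = tpl$n_targets,
                           dropout_prob = tpl$dropout_prob,
                           min_tips = tpl$min_tips, max_tips = tpl$max_tips,
                           seed = sample.int(2^30, 1))
    datasets[[i]] <- ds
    rows[[i]] <- tibble::tibble(replicate = i, !!!as.list(th),
                                n_tips = n_tips(ds$tree),
                                mrca_time = mrca_time(ds$tree),
                                tree_height = tree_height(ds$tree),
                                tree_length = tree_length(ds$tree),
                                seed = ds$seed, attempts = ds$attempts)
  }
  list(truths = dplyr::bind_rows(rows), datasets = datasets)
}
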