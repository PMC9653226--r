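#' Metropolis-Hastings MCMC over editing parameters, trees and population
#' dynamics
#'
#' Jointly samples the posterior of the editing-model parameters (edit rate
#' r, free scarring multipliers, silencing rate l), the
#' birth-death-sampling parameters (lambda, delta, rho) and one time-scaled
#' tree per dataset, targeting
#' \deqn{\prod_d [\,L(tree_d, \theta \mid table_d)\; f_{BDS}(tree_d \mid
#' \lambda,\delta,\rho)\,] \times \pi(\theta, \lambda, \delta, \rho).}
#' Parameters flagged \code{prior_fixed()} are held at their value
#' ("known scarring rates" analyses); with several datasets the remaining
#' parameters are pooled (shared) across datasets while each dataset keeps
#' its own tree.
#'
#' Moves: multiplicative scale moves on each free rate parameter; uniform
#' node-time moves; a scale move on all internal-node ages; narrow exchange;
#' and Wilson-Balding subtree prune-regraft (which can also relocate the
#' root). Scale-move windows are tuned toward an acceptance rate of 0.234
#' during burn-in only. The chain is deterministic given \code{seed}.
#'
#' @param datasets An \code{\link{edit_table}} or list of them (experimental
#'   replicates). All share the sampling time \code{t_s}.
#' @param model An \code{editing_model} template fixing S, the scarring
#'   window and the parameterization (converted internally to multiplier
#'   form).
#' @param priors A \code{\link{prior_spec}}; free vs fixed parameters are
#'   read from it.
#' @param t_s Sampling time (tree height span from origin).
#' @param pooling \code{"shared_params"} (default; required for >1 dataset)
#'   or \code{"none"} (single dataset).
#' @param n_iter Total proposals.
#' @param burnin Fraction of the chain treated as burn-in (tuning happens
#'   only there; summaries drop it).
#' @param thin Record every \code{thin}-th state.
#' @param fixed_trees Optional list of \code{timetree}s (one per dataset):
#'   trees are held fixed and only parameters are sampled.
#' @param likelihood_off Replace the tree likelihood by a constant (prior
#'   recovery validation of the sampler).
#' @param silenced_is_missing Passed to the likelihood.
#' @param condition Conditioning of the tree prior (see
#'   \code{\link{bds_log_density}}).
#' @param seed Integer seed.
#' @param verbose Print progress every ~10% of the chain.
#' @return A \code{scartree_fit}: list with \code{trace} (tibble: iteration,
#'   log_posterior, log_likelihood, log_prior, free parameters, per-dataset
#'   tree height/length), \code{trees} (per-dataset list of sampled
#'   \code{timetree}s aligned with trace rows), \code{acceptance} tibble,
#'   \code{priors}, \code{settings}.
#' @export
run_mcmc <- function(datasets, model, priors, t_s,
                     pooling = c("shared_params", "none"),
                     n_iter = 20000, burnin = 0.1, thin = NULL,
                     fixed_trees = NULL, likelihood_off = FALSE,
                     silenced_is_missing = FALSE,
                     condition = "survival",
                     seed = NULL, verbose = FALSE) {
  pooling <- match.arg(pooling)
  if (inherits(datasets, "edit_table") || (is.data.frame(datasets)))
    datasets <- list(datasets)
  D <- length(datasets)
  stopifnot(D >= 1)
  if (pooling == "none" && D > 1)
    stop("pooling = 'none' supports a single dataset; run replicates separately",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(thin)) thin <- max(1L, floor(n_iter / 1000))
  model <- if (model$parameterization == "clock") as_multiplier_model(model) else model
  S <- model$scar_count
  t1 <- model$window_start; t2 <- model$window_end
  stopifnot(t2 <= t_s + 1e-9)
  ps <- expand_priors(priors, S)
  free <- names(ps)[!vapply(ps, is_fixed_prior, logical(1))]
  par <- vapply(ps, function(p) prior_quantile(p, 0.5), numeric(1))

  # per-dataset state
  sts <- vector("list", D)
  trees_free <- is.null(fixed_trees)
  for (d in seq_len(D)) {
    tab <- datasets[[d]]
    if (trees_free) {
      tr <- NULL
      for (try in 1:20) {
        tr0 <- init_tree(tab, t_s, t2 = t2, jitter = try > 1,
                         silenced_is_missing = silenced_is_missing)
        st0 <- make_tree_state(tr0, tab, silenced_is_missing)
        if (is.finite(state_ll(st0, par, S, t1, t2, likelihood_off))) { tr <- tr0; sts[[d]] <- st0; break }
      }
      if (is.null(tr))
        stop("could not find a starting tree with finite likelihood", call. = FALSE)
    } else {
      sts[[d]] <- make_tree_state(fixed_trees[[d]], tab, silenced_is_missing)
    }
  }
  ll <- vapply(sts, state_ll, numeric(1), par, S, t1, t2, likelihood_off)
  tp <- vapply(sts, state_tp, numeric(1), par, condition)
  lp <- params_log_prior(ps, par, free)
  if (!all(is.finite(c(ll, tp, lp))))
    stop("non-finite posterior at initialization", call. = FALSE)

  # move schedule
  moves <- list()
  for (pn in free)
    moves[[length(moves) + 1]] <- list(type = "scale", par = pn, d = NA,
                                       w = max(2, D))
  if (trees_free) for (d in seq_len(D)) {
    ni <- length(sts[[d]]$internal)
    moves[[length(moves) + 1]] <- list(type = "node_time", d = d, w = max(1, ni / 2))
    moves[[length(moves) + 1]] <- list(type = "root_scale", d = d, w = 1)
    if (ni >= 2) {
      moves[[length(moves) + 1]] <- list(type = "narrow", d = d, w = max(1, ni / 3))
      moves[[length(moves) + 1]] <- list(type = "wb", d = d, w = max(1, ni / 2))
    }
  }
  mw <- vapply(moves, `[[`, numeric(1), "w")
  mprob <- mw / sum(mw)
  n_mv <- length(moves)
  prop_n <- acc_n <- numeric(n_mv)
  tune_w <- rep(1, n_mv)      # log-window of scale-type proposals
  tune_acc <- tune_prop <- numeric(n_mv)
  burn_iter <- floor(burnin * n_iter)

  n_rec <- floor(n_iter / thin)
  free_cols <- matrix(NA_real_, n_rec, length(free),
                      dimnames = list(NULL, free))
  extra <- matrix(NA_real_, n_rec, 3 + 2 * D)
  colnames(extra) <- c("log_posterior", "log_likelihood", "log_prior",
                       paste0(rep(c("tree_height_", "tree_length_"), D),
                              rep(seq_len(D), each = 2)))
  tree_samples <- replicate(D, vector("list", n_rec), simplify = FALSE)
  ri <- 0L

  for (it in seq_len(n_iter)) {
    mi <- sample.int(n_mv, 1, prob = mprob)
    mv <- moves[[mi]]
    prop_n[mi] <- prop_n[mi] + 1
    tune_prop[mi] <- tune_prop[mi] + 1
    accepted <- FALSE
    if (mv$type == "scale") {
      pn <- mv$par
      fac <- exp(tune_w[mi] * (runif(1) - 0.5))
      par2 <- par; par2[pn] <- par[pn] * fac
      lp2 <- params_log_prior(ps, par2, free)
      if (is.finite(lp2)) {
        if (pn %in% c("lambda", "delta", "rho")) {
          tp2 <- vapply(sts, state_tp, numeric(1), par2, condition)
          ll2 <- ll
        } else {
          ll2 <- vapply(sts, state_ll, numeric(1), par2, S, t1, t2, likelihood_off)
          tp2 <- tp
        }
        log_a <- (sum(ll2) + sum(tp2) + lp2) - (sum(ll) + sum(tp) + lp) + log(fac)
        if (is.finite(log_a) && log(runif(1)) < log_a) {
          par <- par2; ll <- ll2; tp <- tp2; lp <- lp2; accepted <- TRUE
        }
      }
    } else {
      d <- mv$d
      prop <- propose_tree_move(sts[[d]], mv$type, tune_w[mi])
      if (!is.null(prop)) {
        st2 <- prop$st
        ll2 <- state_ll(st2, par, S, t1, t2, likelihood_off)
        tp2 <- state_tp(st2, par, condition)
        log_a <- (ll2 + tp2) - (ll[d] + tp[d]) + prop$log_hr
        if (is.finite(log_a) && log(runif(1)) < log_a) {
          sts[[d]] <- st2; ll[d] <- ll2; tp[d] <- tp2; accepted <- TRUE
        }
      }
    }
    if (accepted) { acc_n[mi] <- acc_n[mi] + 1; tune_acc[mi] <- tune_acc[mi] + 1 }
    # tune multiplicative windows during burn-in
    if (it <= burn_iter && moves[[mi]]$type %in% c("scale", "root_scale") &&
        tune_prop[mi] >= 50) {
      rate <- tune_acc[mi] / tune_prop[mi]
      tune_w[mi] <- min(5, max(0.01, tune_w[mi] * exp(rate - 0.234)))
      tune_acc[mi] <- tune_prop[mi] <- 0
    }
    if (it %% thin == 0) {
      ri <- ri + 1L
      free_cols[ri, ] <- par[free]
      hl <- unlist(lapply(sts, function(st)
        c(st$t_s - st$time[st$mrca()], tree_state_length(st))))
      extra[ri, ] <- c(sum(ll) + sum(tp) + lp, sum(ll), sum(tp) + lp, hl)
      for (d in seq_len(D))
        tree_samples[[d]][[ri]] <- state_to_timetree(sts[[d]])
    }
    if (verbose && it %% max(1, floor(n_iter / 10)) == 0)
      message(sprintf("iter %d / %d  log post %.3f", it, n_iter,
                      sum(ll) + sum(tp) + lp))
  }

  trace <- tibble::as_tibble(cbind(iteration = seq_len(ri) * thin,
                                   extra[seq_len(ri), , drop = FALSE],
                                   free_cols[seq_len(ri), , drop = FALSE]))
  acc <- tibble::tibble(
    move = vapply(moves, function(m)
      if (m$type == "scale") paste0("scale_", m$par)
      else paste0(m$type, "_", m$d), character(1)),
    proposed = prop_n, accepted = acc_n,
    rate = ifelse(prop_n > 0, acc_n / prop_n, NA))
  structure(list(trace = trace, trees = tree_samples, acceptance = acc,
                 priors = priors, free = free,
                 settings = list(n_iter = n_iter, burnin = burnin,
                                 thin = thin, t_s = t_s, S = S, t1 = t1,
                                 t2 = t2, D = D, pooling = pooling,
                                 condition = condition,
                                 likelihood_off = likelihood_off,
                                 trees_free = trees_free,
                                 silenced_is_missing = silenced_is_missing),
                 model = model),
            class = "scartree_fit")
}

#' @export
print.scartree_fit <- function(x, ...) {
  cat(sprintf("<scartree_fit> %d recorded states, %d dataset(s), free: %s\n",
              nrow(x$trace), x$settings$D, paste(x$free, collapse = ", ")))
  invisible(x)
}

# ---- internal tree state ----------------------------------------------

# Mutable-ish tree state bundling the timetree with the data and cached
# index vectors used by the likelihood core.
make_tree_state <- function(tree, table, silenced_is_missing = FALSE) {
  stopifnot(inherits(tree, "timetree"))
  tips <- tree_tips(tree)
  states <- align_table_to_tips(table, tree$label[tips],
                                silenced_is_missing = silenced_is_missing)
  nn <- n_nodes(tree)
  tip_row0 <- rep(-1L, nn); tip_row0[tips] <- seq_along(tips) - 1L
  origin <- tree_origin(tree)
  internal <- setdiff(seq_len(nn), c(tips, origin))
  st <- list2env(list(parent = tree$parent, time = tree$time,
                      label = tree$label, t_s = tree$t_s,
                      kids = tree_children(tree), origin = origin,
                      tips = tips, internal = internal,
                      states = states, tip_row0 = tip_row0, m = ncol(states)),
                 parent = emptyenv())
  st$mrca <- function() st$kids[[st$origin]][1L]
  st
}

state_ll <- function(st, par, S, t1, t2, likelihood_off) {
  if (likelihood_off) return(0)
  mult <- multipliers_from_params(par, S)
  parent0 <- ifelse(is.na(st$parent), -1L, st$parent - 1L)
  porder0 <- order(st$time, decreasing = TRUE) - 1L
  sum(prune_loglik_cpp(as.integer(parent0), as.integer(porder0), st$time,
                       st$tip_row0, st$states, par[["r"]], par[["l"]],
                       matrix(mult, ncol = 1), integer(st$m), t1, t2))
}

state_tp <- function(st, par, condition) {
  bds_log_density_ages(st$t_s - st$time[st$internal], par[["lambda"]],
                       par[["delta"]], par[["rho"]], st$t_s,
                       condition = condition)
}

params_log_prior <- function(ps, par, free) {
  if (!length(free)) return(0)
  sum(vapply(free, function(pn) prior_density(ps[[pn]], par[[pn]]), numeric(1)))
}

tree_state_length <- function(st) {
  mrca <- st$mrca()
  below <- setdiff(seq_along(st$parent), c(st$origin, mrca))
  sum(st$time[below] - st$time[st$parent[below]])
}

state_to_timetree <- function(st) {
  structure(list(parent = st$parent, time = st$time, label = st$label,
                 t_s = st$t_s), class = "timetree")
}

clone_state <- function(st) {
  st2 <- list2env(as.list(st), parent = emptyenv())
  st2$mrca <- function() st2$kids[[st2$origin]][1L]
  st2
}

# UPGMA-like heuristic start tree: topology from average-linkage clustering
# of Hamming distances. All divergence times are placed inside the scarring
# window (any tip states have positive probability there: a cherry joined
# after the window cannot explain tips carrying different scars), in an
# order consistent with the topology.
init_tree <- function(table, t_s, t2 = t_s, jitter = FALSE,
                      silenced_is_missing = FALSE) {
  mat <- edit_table_states(table, silenced_is_missing = silenced_is_missing)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cmp <- mat[i, ] != mat[j, ]
    dm[i, j] <- dm[j, i] <- mean(cmp, na.rm = TRUE)
  }
  dm[is.nan(dm)] <- 0
  if (jitter) dm <- dm + matrix(runif(n * n, 0, 0.05), n, n)
  dm <- (dm + t(dm)) / 2
  rownames(dm) <- colnames(dm) <- rownames(mat)
  phy <- phangorn::upgma(stats::as.dist(dm))
  topo_to_timetree(phy, t_s, max_time = 0.95 * (if (t2 > 0) min(t2, t_s) else t_s))
}

# timetree from a phylo topology with internal times evenly spread in
# (0, max_time), parents older than children.
topo_to_timetree <- function(phy, t_s, max_time) {
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  parent <- rep(NA_integer_, nn + 1L)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  origin <- nn + 1L
  parent[nt + 1L] <- origin
  depth <- integer(nn)
  for (e in seq_len(nrow(phy$edge)))
    depth[phy$edge[e, 2]] <- NA                 # filled below
  depth[nt + 1L] <- 0L
  ord <- order(ape::node.depth.edgelength(phy)) # parents before children
  for (nd in ord) if (!is.na(parent[nd]) && parent[nd] != origin)
    depth[nd] <- depth[parent[nd]] + 1L
  internal <- (nt + 1L):nn
  o <- internal[order(depth[internal], decreasing = TRUE)]
  ni <- length(o)
  time <- numeric(nn + 1L)
  time[seq_len(nt)] <- t_s
  time[o] <- max_time * (ni:1) / (ni + 1)
  time[origin] <- 0
  label <- c(phy$tip.label, rep(NA_character_, nn - nt + 1L))
  new_timetree(parent, time, label, t_s)
}

# ---- tree proposals ----------------------------------------------------

# Returns NULL (auto-reject) or list(st = proposed state, log_hr).
propose_tree_move <- function(st, type, w) {
  switch(type,
    node_time = {
      nd <- st$internal[sample.int(length(st$internal), 1)]
      lo <- st$time[st$parent[nd]]
      hi <- min(st$time[st$kids[[nd]]])
      if (hi <= lo) return(NULL)
      st2 <- clone_state(st)
      st2$time[nd] <- runif(1, lo, hi)
      list(st = st2, log_hr = 0)
    },
    root_scale = {
      fac <- exp(w * (runif(1) - 0.5))
      ages <- st$t_s - st$time[st$internal]
      new_ages <- ages * fac
      if (max(new_ages) >= st$t_s) return(NULL)
      st2 <- clone_state(st)
      st2$time[st$internal] <- st$t_s - new_ages
      list(st = st2, log_hr = length(st$internal) * log(fac))
    },
    narrow = {
      cand <- st$internal[st$parent[st$internal] != st$origin]
      if (!length(cand)) return(NULL)
      p <- cand[sample.int(length(cand), 1)]
      g <- st$parent[p]
      s <- setdiff(st$kids[[g]], p)
      cc <- st$kids[[p]][sample.int(2, 1)]
      if (st$time[s] <= st$time[p]) return(NULL)
      st2 <- clone_state(st)
      st2$parent[cc] <- g; st2$parent[s] <- p
      st2$kids[[g]] <- c(setdiff(st2$kids[[g]], s), cc)
      st2$kids[[p]] <- c(setdiff(st2$kids[[p]], cc), s)
      list(st = st2, log_hr = 0)
    },
    wb = {
      mrca <- st$mrca()
      elig <- setdiff(seq_along(st$parent), c(st$origin, mrca))
      if (!length(elig)) return(NULL)
      i <- elig[sample.int(length(elig), 1)]
      p <- st$parent[i]
      j <- setdiff(st$kids[[p]], i)
      g <- st$parent[p]
      L_old <- min(st$time[j], st$time[i]) - st$time[g]
      desc <- subtree_nodes(st, i)
      cand <- setdiff(seq_along(st$parent), c(st$origin, p, desc))
      cc <- cand[sample.int(length(cand), 1)]
      pa_c <- if (cc == j) g else st$parent[cc]
      lo <- st$time[pa_c]
      hi <- min(st$time[cc], st$time[i])
      if (hi <= lo) return(NULL)
      t_new <- runif(1, lo, hi)
      st2 <- clone_state(st)
      # detach p: g adopts j
      st2$parent[j] <- g
      st2$kids[[g]] <- c(setdiff(st2$kids[[g]], p), j)
      # insert p on the edge above cc
      st2$parent[p] <- pa_c
      st2$parent[cc] <- p
      st2$kids[[pa_c]] <- c(setdiff(st2$kids[[pa_c]], cc), p)
      st2$kids[[p]] <- c(i, cc)
      st2$time[p] <- t_new
      list(st = st2, log_hr = log(hi - lo) - log(L_old))
    })
}

subtree_nodes <- function(st, i) {
  out <- i; stack <- st$kids[[i]]
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    out <- c(out, nd)
    stack <- c(stack, st$kids[[nd]])
  }
  out
}
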