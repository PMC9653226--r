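#' Shortest (highest-density) posterior interval
#'
#' Empirical HPD via the sorted-window method: the shortest contiguous
#' window of sorted draws containing \code{level} of them.
#'
#' @param x Numeric sample.
#' @param level Mass to cover (default 0.95).
#' @return Numeric length-2 vector (lower, upper).
#' @export
hpd_interval <- function(x, level = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' Effective sample size via the autocorrelation time
#'
#' ESS = n / (1 + 2 sum of autocorrelations), truncated at the first
#' negative autocorrelation.
#'
#' @param x Numeric sample (one chain).
#' @return ESS (NA with attribute \code{too_short} when n < 10).
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10) return(structure(NA_real_, too_short = TRUE))
  if (sd(x) == 0) return(n)
  a <- acf(x, lag.max = min(n - 1, 1000), plot = FALSE)$acf[-1]
  neg <- which(a < 0)[1]
  if (!is.na(neg)) a <- a[seq_len(neg - 1)]
  max(1, n / (1 + 2 * sum(a)))
}

#' Posterior summaries of a fitted chain
#'
#' Per-parameter posterior median, HPD interval and ESS, after discarding
#' the burn-in fraction recorded in the fit.
#'
#' @param fit A \code{scartree_fit} (or a data frame trace).
#' @param level HPD mass.
#' @param parameters Columns to summarize; defaults to all free parameters
#'   plus per-dataset tree height and length.
#' @param drop_burnin Discard the burn-in fraction (default TRUE for fits).
#' @return Tibble: parameter, median, lower, upper, ess, ess_too_short.
#' @export
summarize_posterior <- function(fit, level = 0.95, parameters = NULL,
                                drop_burnin = TRUE) {
  tr <- posterior_draws(fit, drop_burnin = drop_burnin)
  if (is.null(parameters))
    parameters <- setdiff(names(tr), c("iteration", "log_posterior",
                                       "log_likelihood", "log_prior"))
  purrr::map_dfr(parameters, function(pn) {
    x <- tr[[pn]]
    h <- hpd_interval(x, level)
    e <- effective_size(x)
    tibble::tibble(parameter = pn, median = median(x),
                   lower = h[1], upper = h[2],
                   ess = as.numeric(e),
                   ess_too_short = isTRUE(attr(e, "too_short")))
  })
}

#' Posterior draws of a fitted chain
#'
#' The recorded trace as a tibble, with the burn-in fraction dropped by
#' default; data frames pass through untouched.
#'
#' @param fit A \code{scartree_fit} (or a data frame trace).
#' @param drop_burnin Discard the burn-in fraction recorded in the fit.
#' @return A tibble of posterior draws.
#' @export
posterior_draws <- function(fit, drop_burnin = TRUE) {
  if (is.data.frame(fit)) return(tibble::as_tibble(fit))
  stopifnot(inherits(fit, "scartree_fit"))
  tr <- fit$trace
  if (drop_burnin) {
    cut <- fit$settings$burnin * fit$settings$n_iter
    tr <- tr[tr$iteration > cut, , drop = FALSE]
  }
  tr
}

# Post-burn-in sampled trees for one dataset.
posterior_trees <- function(fit, dataset = 1, drop_burnin = TRUE) {
  stopifnot(inherits(fit, "scartree_fit"))
  trees <- fit$trees[[dataset]]
  if (drop_burnin) {
    cut <- fit$settings$burnin * fit$settings$n_iter
    keep <- fit$trace$iteration > cut
    trees <- trees[keep]
  }
  trees[!vapply(trees, is.null, logical(1))]
}

#' @export
tidy.scartree_fit <- function(x, level = 0.95, ...) {
  summarize_posterior(x, level = level)
}

#' @export
glance.scartree_fit <- function(x, ...) {
  tr <- posterior_draws(x)
  tibble::tibble(n_iter = x$settings$n_iter,
                 n_recorded = nrow(x$trace),
                 n_datasets = x$settings$D,
                 n_free = length(x$free),
                 accept_rate = sum(x$acceptance$accepted) /
                   sum(x$acceptance$proposed),
                 median_log_posterior = median(tr$log_posterior))
}

#' 95% credible set of tree topologies
#'
#' Builds the smallest set of unranked labelled topologies whose posterior
#' probabilities sum to at least \code{level}: unique topologies are added
#' in order of decreasing posterior probability until the target mass is
#' reached.
#'
#' @param trees A list of \code{timetree} samples, or a \code{scartree_fit}
#'   (post-burn-in trees of \code{dataset} are used).
#' @param level Target mass (default 0.95).
#' @param dataset Dataset index when \code{trees} is a fit.
#' @return Tibble (topology key, count, probability, cumulative), minimal
#'   prefix reaching \code{level}; the full ranking is in
#'   \code{attr(, "all_topologies")}.
#' @export
credible_tree_set <- function(trees, level = 0.95, dataset = 1) {
  if (inherits(trees, "scartree_fit")) trees <- posterior_trees(trees, dataset)
  stopifnot(length(trees) >= 1)
  keys <- vapply(trees, topology_key, character(1))
  tab <- sort(table(keys), decreasing = TRUE)
  all_topo <- tibble::tibble(topology = names(tab),
                             count = as.integer(tab),
                             probability = as.integer(tab) / length(keys))
  all_topo$cumulative <- cumsum(all_topo$probability)
  n_keep <- which(all_topo$cumulative >= level - 1e-12)[1]
  if (is.na(n_keep)) n_keep <- nrow(all_topo)
  out <- all_topo[seq_len(n_keep), , drop = FALSE]
  attr(out, "all_topologies") <- all_topo
  out
}

#' Posterior support of clades
#'
#' Fraction of sampled trees containing each clade (tip-label set); used to
#' score the posterior probability of true internal nodes.
#'
#' @param trees List of \code{timetree} samples or a \code{scartree_fit}.
#' @param min_age Only count clades whose node age (t_s - node time) exceeds
#'   this (configurable node-age filter; default 0 = all).
#' @param dataset Dataset index when a fit is given.
#' @return Tibble (clade = "a|b|c" sorted labels, support).
#' @export
clade_support <- function(trees, min_age = 0, dataset = 1) {
  if (inherits(trees, "scartree_fit")) trees <- posterior_trees(trees, dataset)
  n <- length(trees)
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    kids <- tree_children(tr)
    tips <- tree_tips(tr)
    nn <- length(tr$parent)
    below <- vector("list", nn)
    for (nd in order(tr$time, decreasing = TRUE)) {
      below[[nd]] <- if (nd %in% tips) tr$label[nd]
                     else sort(unlist(lapply(kids[[nd]], function(ch) below[[ch]])))
      if (!(nd %in% tips) && length(kids[[nd]]) == 2L &&
          length(below[[nd]]) >= 2L &&
          (tr$t_s - tr$time[nd]) > min_age) {
        key <- paste(below[[nd]], collapse = "|")
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  keys <- ls(counts)
  tibble::tibble(clade = keys,
                 support = unname(vapply(keys, function(k) counts[[k]] / n,
                                         numeric(1)))) |>
    dplyr::arrange(dplyr::desc(.data$support))
}

#' Posterior support of the true clades of a reference tree
#'
#' @param trees Tree samples (or fit).
#' @param true_tree The reference \code{timetree}.
#' @param min_age Node-age filter applied to the true clades.
#' @param dataset Dataset index when a fit is given.
#' @return Tibble (clade, support) for each qualifying true clade (support 0
#'   when never sampled).
#' @export
true_clade_support <- function(trees, true_tree, min_age = 0, dataset = 1) {
  cs <- clade_support(trees, min_age = 0, dataset = dataset)
  kids <- tree_children(true_tree)
  tips <- tree_tips(true_tree)
  nn <- length(true_tree$parent)
  below <- vector("list", nn)
  rows <- list()
  for (nd in order(true_tree$time, decreasing = TRUE)) {
    below[[nd]] <- if (nd %in% tips) true_tree$label[nd]
                   else sort(unlist(lapply(kids[[nd]], function(ch) below[[ch]])))
    if (!(nd %in% tips) && length(kids[[nd]]) == 2L &&
        length(below[[nd]]) >= 2L &&
        (true_tree$t_s - true_tree$time[nd]) > min_age)
      rows[[length(rows) + 1]] <- paste(below[[nd]], collapse = "|")
  }
  keys <- unlist(rows)
  sup <- cs$support[match(keys, cs$clade)]
  sup[is.na(sup)] <- 0
  tibble::tibble(clade = keys, support = sup)
}

#' Write sampled trees as a NEXUS tree log
#'
#' One tree per retained MCMC sample, with a translate table, readable by
#' common tree viewers.
#'
#' @param fit A \code{scartree_fit}.
#' @param path Output file.
#' @param dataset Dataset index.
#' @export
write_tree_log <- function(fit, path, dataset = 1) {
  trees <- posterior_trees(fit, dataset, drop_burnin = FALSE)
  phys <- lapply(trees, as.phylo.timetree)
  class(phys) <- "multiPhylo"
  ape::write.nexus(phys, file = path, translate = TRUE)
  invisible(path)
}
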