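#' Phylogenetic likelihood of editing parameters and a time-scaled tree
#'
#' Computes the log-likelihood of a time-scaled tree and editing-model
#' parameters given the observed edit table, by the pruning algorithm. Each
#' of the m targets evolves independently down the tree under the
#' time-dependent editing model; branches are cut at the scarring-window
#' boundaries so that each segment is time-homogeneous and its transition
#' matrix has the closed form of \code{\link{transition_probabilities}}. The
#' lineage at the origin is unedited with probability one, so the per-target
#' likelihood is the unedited entry of the origin partial vector. Missing
#' observations contribute an all-ones partial (missing at random). Per-node,
#' per-site scaling keeps partial likelihoods from underflowing on tables
#' with hundreds of cells.
#'
#' @param tree A \code{\link{new_timetree}} whose tip labels match the
#'   table's cell ids.
#' @param table An \code{\link{edit_table}} (cells x targets).
#' @param model An \code{editing_model} (shared across targets) or
#'   \code{\link{site_models}} with one model per target; the scarring window
#'   must lie within \code{[0, t_s]}.
#' @param silenced_is_missing Treat observed silenced states (1) as missing
#'   (RNA-readout ambiguity); default keeps them as data.
#' @param on_impossible What to do when the data have probability zero under
#'   the model (e.g. a scarred tip whose whole lineage lies outside the
#'   scarring window): \code{"error"} raises a diagnostic error,
#'   \code{"neg_inf"} returns \code{-Inf} (used by the MCMC).
#' @return \code{tree_log_likelihood}: the total log-likelihood;
#'   \code{per_site_log_likelihoods}: a numeric vector of the m per-target
#'   log-likelihood terms (summing to the total).
#' @export
tree_log_likelihood <- function(tree, table, model,
                                silenced_is_missing = FALSE,
                                on_impossible = c("error", "neg_inf")) {
  sum(per_site_log_likelihoods(tree, table, model,
                               silenced_is_missing = silenced_is_missing,
                               on_impossible = on_impossible))
}

#' @rdname tree_log_likelihood
#' @export
per_site_log_likelihoods <- function(tree, table, model,
                                     silenced_is_missing = FALSE,
                                     on_impossible = c("error", "neg_inf")) {
  on_impossible <- match.arg(on_impossible)
  stopifnot(inherits(tree, "timetree"))
  tips <- tree_tips(tree)
  states <- align_table_to_tips(table, tree$label[tips],
                                silenced_is_missing = silenced_is_missing)
  sm <- as_site_models(model, ncol(states))
  check_states_in_range(states, sm)
  w <- c(sm$models[[1]]$window_start, sm$models[[1]]$window_end)
  if (w[1] < 0 || w[2] > tree$t_s + 1e-9)
    stop("scarring window must lie within [0, t_s]", call. = FALSE)
  args <- likelihood_args(tree, states, sm)
  ll <- prune_loglik_cpp(args$parent0, args$porder0, tree$time, args$tip_row0,
                         states, args$r, args$l, args$smat, args$group0,
                         w[1], w[2])
  if (any(!is.finite(ll)) && on_impossible == "error")
    stop(sprintf(paste0("data have zero likelihood under the model at target(s) %s ",
                        "(e.g. a scar on a lineage with no scarring-window overlap)"),
                 paste(which(!is.finite(ll)), collapse = ", ")), call. = FALSE)
  as.numeric(ll)
}

check_states_in_range <- function(states, sm) {
  S <- sm$models[[1]]$scar_count
  mx <- suppressWarnings(max(states, na.rm = TRUE))
  if (is.finite(mx) && mx > S + 1L)
    stop(sprintf("state %d out of range for S = %d scar outcomes", mx, S),
         call. = FALSE)
}

# Precompute the C++ call arguments that depend on tree shape and model
# grouping (0-based indices; postorder = decreasing node time).
likelihood_args <- function(tree, states, sm) {
  nn <- n_nodes(tree)
  tips <- tree_tips(tree)
  tip_row0 <- rep(-1L, nn)
  tip_row0[tips] <- seq_along(tips) - 1L   # states rows are in tip order
  parent0 <- ifelse(is.na(tree$parent), -1L, tree$parent - 1L)
  porder0 <- order(tree$time, decreasing = TRUE) - 1L
  grp <- model_groups(sm)
  list(parent0 = as.integer(parent0), porder0 = as.integer(porder0),
       tip_row0 = as.integer(tip_row0), r = grp$r, l = grp$l,
       smat = grp$smat, group0 = grp$group0)
}

# Collapse identical per-site models into groups for the C++ core.
model_groups <- function(sm) {
  key <- vapply(sm$models, function(mm)
    paste(signif(c(mm$edit_rate, mm$silencing_rate, mm$scarring_multipliers), 15),
          collapse = "|"), character(1))
  uk <- unique(key)
  idx <- match(key, uk)
  first <- match(uk, key)
  S <- sm$models[[1]]$scar_count
  smat <- vapply(first, function(i) sm$models[[i]]$scarring_multipliers,
                 numeric(S))
  smat <- matrix(smat, nrow = S)
  list(r = vapply(first, function(i) sm$models[[i]]$edit_rate, numeric(1)),
       l = vapply(first, function(i) sm$models[[i]]$silencing_rate, numeric(1)),
       smat = smat, group0 = as.integer(idx - 1L))
}
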