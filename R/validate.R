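#' Well-calibrated validation of the inference machinery
#'
#' Draws truths from the priors, simulates a dataset per replicate, runs the
#' MCMC under the same priors, and scores how often each free parameter's
#' true value falls inside its 95% HPD interval. For a correct
#' implementation the coverage converges to the nominal level. With
#' \code{fix_trees = TRUE} the tree is fixed to the simulated truth and only
#' the rate parameters are sampled (a fast smoke version of the full study).
#'
#' @param priors A \code{\link{prior_spec}} used both to draw truths and as
#'   inference priors.
#' @param n_replicates Number of replicates.
#' @param template Study conditions, as in
#'   \code{\link{run_calibrated_study}}.
#' @param n_iter,burnin MCMC settings per replicate.
#' @param fix_trees Fix each tree to its simulated truth.
#' @param level Credible level.
#' @param seed Integer seed.
#' @param parameters Parameters to score (default: all free in priors).
#' @param verbose Progress messages.
#' @return List: \code{results} (replicate x parameter tibble with truth,
#'   median, lower, upper), \code{coverage} (per-parameter coverage %, with
#'   a binomial 95% band for the replicate count), \code{truths}.
#' @export
well_calibrated_validation <- function(priors, n_replicates, template = list(),
                                       n_iter = 4000, burnin = 0.2,
                                       fix_trees = TRUE, level = 0.95,
                                       seed = NULL, parameters = NULL,
                                       verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  study <- run_calibrated_study(priors, n_replicates, template,
                                seed = sample.int(2^30, 1))
  tpl <- utils::modifyList(list(S = 2, window_start = 0, window_end = 16,
                                t_s = 32, min_tips = 2, max_tips = Inf),
                           template)
  # the tree prior must condition on the same tip-count retention rule the
  # simulator used, otherwise coverage is miscalibrated for lambda and rho
  cond <- c(tpl$min_tips, tpl$max_tips)
  ps <- expand_priors(priors, tpl$S)
  free <- names(ps)[!vapply(ps, is_fixed_prior, logical(1))]
  if (is.null(parameters)) parameters <- free
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    ds <- study$datasets[[i]]
    truth <- study$truths[i, ]
    model <- editing_model(
      edit_rate = prior_quantile(ps$r, 0.5),
      scarring_multipliers = multipliers_from_params(
        unlist(truth), tpl$S),      # free multipliers are re-estimated below
      window_start = tpl$window_start, window_end = tpl$window_end)
    fit <- run_mcmc(ds$table, model, priors, t_s = tpl$t_s,
                    n_iter = n_iter, burnin = burnin,
                    fixed_trees = if (fix_trees) list(ds$tree) else NULL,
                    condition = cond, seed = sample.int(2^30, 1))
    sm <- summarize_posterior(fit, level = level)
    rows[[i]] <- purrr::map_dfr(parameters, function(pn) {
      row <- sm[sm$parameter == pn, ]
      tibble::tibble(replicate = i, parameter = pn,
                     truth = truth[[pn]], median = row$median,
                     lower = row$lower, upper = row$upper)
    })
    if (verbose) message(sprintf("replicate %d / %d", i, n_replicates))
  }
  results <- dplyr::bind_rows(rows)
  coverage <- results |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(n = dplyr::n(),
                     covered = sum(.data$truth >= .data$lower &
                                   .data$truth <= .data$upper),
                     .groups = "drop") |>
    dplyr::mutate(
      coverage = 100 * .data$covered / .data$n,
      band_lower = 100 * stats::qbinom(0.025, .data$n, level) / .data$n,
      band_upper = 100 * stats::qbinom(0.975, .data$n, level) / .data$n)
  list(results = results, coverage = coverage, truths = study$truths)
}

#' Fixed-parameter recovery study (truth-versus-estimate correlations)
#'
#' Simulates replicates under truths drawn from a study grid
#' (\code{truth_priors}), infers trees and parameters under weakly
#' informative priors (\code{infer_priors}), and assembles a
#' \code{\link{recovery_report}} tracking tree height, tree length, birth
#' rate and sampling proportion, stratified by whether the true MRCA falls
#' inside the editing window. Scarring multipliers are held at their true
#' values (the editing-outcome frequencies are treated as known).
#'
#' @param n_replicates Replicates to simulate.
#' @param truth_priors \code{prior_spec} defining the study grid of truths.
#' @param infer_priors \code{prior_spec} used by the MCMC.
#' @param template Study conditions (see
#'   \code{\link{run_calibrated_study}}).
#' @param n_iter,burnin Per-replicate MCMC settings.
#' @param seed Integer seed.
#' @param verbose Progress messages.
#' @return List: \code{report} (a \code{recovery_report}), \code{truths},
#'   \code{fits}.
#' @export
recovery_study <- function(n_replicates, truth_priors, infer_priors,
                           template = list(), n_iter = 25000, burnin = 0.2,
                           seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  study <- run_calibrated_study(truth_priors, n_replicates, template,
                                seed = sample.int(2^30, 1))
  tpl <- utils::modifyList(list(S = 2, window_start = 0, window_end = 16,
                                t_s = 32), template)
  fits <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    truth <- unlist(study$truths[i, ])
    model <- editing_model(
      edit_rate = truth[["r"]],
      scarring_multipliers = multipliers_from_params(truth, tpl$S),
      window_start = tpl$window_start, window_end = tpl$window_end)
    pri <- infer_priors
    pri$s <- prior_fixed(1)   # multipliers known; values come from the model
    pri$s$pars$value <- multipliers_from_params(truth, tpl$S)[1]
    fits[[i]] <- run_mcmc(study$datasets[[i]]$table, model, pri,
                          t_s = tpl$t_s, n_iter = n_iter, burnin = burnin,
                          seed = sample.int(2^30, 1))
    if (verbose) message(sprintf("replicate %d / %d (%d tips)", i,
                                 n_replicates, n_tips(study$datasets[[i]]$tree)))
  }
  truths <- study$truths
  report <- recovery_report(truths, fits, t2 = tpl$window_end)
  list(report = report, truths = truths, fits = fits)
}

#' Scenario comparison: value of prior knowledge and replicates
#'
#' Runs three analyses on a common simulated batch, mirroring increasing
#' amounts of independent information: (A) a single alignment with the
#' scarring multipliers estimated; (B) a single alignment with the true
#' multipliers supplied; (C) \code{n_pooled} replicate alignments with true
#' multipliers, editing and population parameters pooled across replicates
#' while each keeps its own tree. Returns per-replicate estimates of the
#' birth rate, sampling proportion and (first-dataset) tree height/length
#' under each scenario.
#'
#' @param truth Named list/vector of true parameters (r, lambda, rho, and
#'   the free multipliers s_1..; delta and l default to 0).
#' @param n_replicates Number of truth-level replicates (batches).
#' @param n_pooled Alignments per batch used by scenario C.
#' @param template Study conditions.
#' @param priors Weakly informative priors (scenario A; B and C fix the
#'   multipliers).
#' @param n_iter,burnin MCMC settings (C uses \code{n_iter_pooled}).
#' @param n_iter_pooled Chain length for the pooled analysis.
#' @param seed Integer seed.
#' @param verbose Progress messages.
#' @return Tibble: scenario, replicate, parameter, truth, median, lower,
#'   upper.
#' @export
scenario_study <- function(truth, n_replicates, n_pooled = 10,
                           template = list(), priors = prior_spec(),
                           n_iter = 20000, n_iter_pooled = NULL,
                           burnin = 0.2, seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_iter_pooled)) n_iter_pooled <- 3 * n_iter
  tpl <- utils::modifyList(list(S = 2, window_start = 0, window_end = 16,
                                t_s = 32, n_targets = 20, dropout_prob = 0,
                                min_tips = 4, max_tips = 25), template)
  cond <- c(tpl$min_tips, tpl$max_tips)   # match the retention rule
  truth <- unlist(truth)
  if (!"l" %in% names(truth)) truth[["l"]] <- 0
  if (!"delta" %in% names(truth)) truth[["delta"]] <- 0
  mult <- multipliers_from_params(truth, tpl$S)
  model <- editing_model(truth[["r"]], mult, silencing_rate = truth[["l"]],
                         window_start = tpl$window_start,
                         window_end = tpl$window_end)
  bds <- bds_params(truth[["lambda"]], truth[["delta"]], truth[["rho"]],
                    tpl$t_s)
  pri_known_s <- priors; pri_known_s$s <- prior_fixed(mult[1])
  rows <- list()
  grab <- function(fit, scenario, rep_i, truths_tree) {
    sm <- summarize_posterior(fit)
    purrr::map_dfr(c("lambda", "rho", "tree_height", "tree_length"),
                   function(pn) {
      col <- if (pn %in% c("tree_height", "tree_length")) paste0(pn, "_1") else pn
      row <- sm[sm$parameter == col, ]
      tv <- switch(pn, lambda = truth[["lambda"]], rho = truth[["rho"]],
                   tree_height = truths_tree[["tree_height"]],
                   tree_length = truths_tree[["tree_length"]])
      tibble::tibble(scenario = scenario, replicate = rep_i, parameter = pn,
                     truth = tv, median = row$median, lower = row$lower,
                     upper = row$upper)
    })
  }
  for (i in seq_len(n_replicates)) {
    datasets <- lapply(seq_len(n_pooled), function(j)
      simulate_dataset(bds, model, n_targets = tpl$n_targets,
                       dropout_prob = tpl$dropout_prob,
                       min_tips = tpl$min_tips, max_tips = tpl$max_tips,
                       seed = sample.int(2^30, 1)))
    tt <- list(tree_height = tree_height(datasets[[1]]$tree),
               tree_length = tree_length(datasets[[1]]$tree))
    fitA <- run_mcmc(datasets[[1]]$table, model, priors, t_s = tpl$t_s,
                     n_iter = n_iter, burnin = burnin, condition = cond,
                     seed = sample.int(2^30, 1))
    fitB <- run_mcmc(datasets[[1]]$table, model, pri_known_s, t_s = tpl$t_s,
                     n_iter = n_iter, burnin = burnin, condition = cond,
                     seed = sample.int(2^30, 1))
    fitC <- run_mcmc(lapply(datasets, `[[`, "table"), model, pri_known_s,
                     t_s = tpl$t_s, pooling = "shared_params",
                     n_iter = n_iter_pooled, burnin = burnin,
                     condition = cond, seed = sample.int(2^30, 1))
    rows[[length(rows) + 1]] <- grab(fitA, "A", i, tt)
    rows[[length(rows) + 1]] <- grab(fitB, "B", i, tt)
    rows[[length(rows) + 1]] <- grab(fitC, "C", i, tt)
    if (verbose) message(sprintf("batch %d / %d", i, n_replicates))
  }
  dplyr::bind_rows(rows)
}

#' Scenario scoreboard (RMSE, bias, HPD width, coverage)
#'
#' @param estimates Output of \code{\link{scenario_study}}.
#' @return Tibble: scenario x parameter with rmse, bias, mean HPD width,
#'   coverage %.
#' @export
scenario_metrics <- function(estimates) {
  estimates |>
    dplyr::group_by(.data$scenario, .data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      rmse = sqrt(mean((.data$median - .data$truth)^2)),
      bias = mean(.data$median - .data$truth),
      mean_hpd_width = mean(.data$upper - .data$lower),
      coverage = 100 * mean(.data$truth >= .data$lower &
                            .data$truth <= .data$upper),
      .groups = "drop")
}
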