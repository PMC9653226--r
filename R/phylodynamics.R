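#' Birth-death-sampling parameters
#'
#' Parameters of the constant-rate birth-death process with incomplete
#' sampling at a single time point: cell division (birth) rate \code{lambda},
#' apoptosis (death) rate \code{delta}, and the probability \code{rho} that
#' an extant cell is sampled at the end of the experiment. \code{origin_time}
#' is the duration from the origin (a single precursor cell) to sampling.
#'
#' @param birth_rate Division rate lambda >= 0, per unit time.
#' @param death_rate Apoptosis rate delta >= 0.
#' @param sampling_proportion rho in (0, 1].
#' @param origin_time Duration origin -> sampling, > 0.
#' @return An object of class \code{bds_params}.
#' @export
bds_params <- function(birth_rate, death_rate = 0, sampling_proportion = 1,
                       origin_time) {
  stopifnot(birth_rate >= 0, death_rate >= 0,
            sampling_proportion > 0, sampling_proportion <= 1,
            origin_time > 0)
  structure(list(birth_rate = as.numeric(birth_rate),
                 death_rate = as.numeric(death_rate),
                 sampling_proportion = as.numeric(sampling_proportion),
                 origin_time = as.numeric(origin_time)),
            class = "bds_params")
}

#' @export
print.bds_params <- function(x, ...) {
  cat(sprintf("<bds_params> lambda = %g, delta = %g, rho = %g, origin time = %g\n",
              x$birth_rate, x$death_rate, x$sampling_proportion, x$origin_time))
  invisible(x)
}

# p0(t): probability that a single lineage starting t before sampling leaves
# no sampled descendant; p1(t): exactly one, with the sampled-ancestor path.
# Constant-rate formulas; the lambda == delta limit is handled separately.
bds_p0 <- function(t, lambda, delta, rho) {
  if (abs(lambda - delta) < 1e-12) {
    1 - rho / (1 + rho * lambda * t)
  } else {
    g <- lambda - delta
    1 - rho * g / (rho * lambda + (lambda * (1 - rho) - delta) * exp(-g * t))
  }
}

bds_log_p1 <- function(t, lambda, delta, rho) {
  if (abs(lambda - delta) < 1e-12) {
    log(rho) - 2 * log1p(rho * lambda * t)
  } else {
    g <- lambda - delta
    log(rho) + 2 * log(g) - g * t -
      2 * log(rho * lambda + (lambda * (1 - rho) - delta) * exp(-g * t))
  }
}

# Log density given internal-node ages (before sampling) and the origin age.
# condition: "none", "survival" (N >= 1), or c(min, max) conditioning on the
# sampled tip count falling in a range. The tip count of the constant-rate
# process is geometric given survival: P(N = n) = (1 - p0)(1 - A) A^(n-1)
# with A = 1 - p1/(1 - p0), which gives the range mass in closed form.
bds_log_density_ages <- function(ages, lambda, delta, rho, origin_time,
                                 condition = "survival") {
  if (lambda <= 0) return(-Inf)
  ll <- bds_log_p1(origin_time, lambda, delta, rho) +
    sum(log(lambda) + bds_log_p1(ages, lambda, delta, rho))
  if (is.numeric(condition)) {
    ll <- ll - log(bds_tip_range_prob(condition[1], condition[2],
                                      lambda, delta, rho, origin_time))
  } else if (condition == "survival") {
    p0 <- bds_p0(origin_time, lambda, delta, rho)
    ll <- ll - log1p(-p0)
  }
  ll
}

#' Probability that the sampled tip count falls in a range
#'
#' Closed-form P(min <= N <= max) for the constant-rate
#' birth-death-sampling process started from one lineage at the origin; the
#' tip count is geometric conditional on survival.
#'
#' @param n_min,n_max Tip-count bounds (n_max may be Inf).
#' @param lambda,delta,rho,origin_time Process parameters.
#' @return Probability.
#' @export
bds_tip_range_prob <- function(n_min, n_max, lambda, delta, rho, origin_time) {
  p0 <- bds_p0(origin_time, lambda, delta, rho)
  p1 <- exp(bds_log_p1(origin_time, lambda, delta, rho))
  A <- 1 - p1 / (1 - p0)
  mn <- max(1, n_min)
  hi <- if (is.finite(n_max)) A^n_max else 0
  (1 - p0) * (A^(mn - 1) - hi) + (if (n_min <= 0) p0 else 0)
}

#' Birth-death-sampling tree prior density
#'
#' Log probability density of a time-scaled sampled tree under the
#' constant-rate birth-death process started from one lineage at the origin,
#' with each extant cell sampled independently with probability rho at the
#' sampling time. By default the density is conditioned on the origin time
#' and on at least one cell being sampled (survival), matching how simulated
#' datasets are retained. The density is over ranked oriented trees; label
#' and ranking constants shared by all trees on the same tips are omitted,
#' as is standard for MCMC use.
#'
#' @param tree A \code{timetree} (ultrametric, tips at \code{t_s}).
#' @param params A \code{\link{bds_params}}; \code{origin_time} must equal
#'   the tree's \code{t_s}.
#' @param condition \code{"survival"} (default), \code{"none"}, or a
#'   numeric \code{c(min, max)} to condition on the sampled tip count
#'   falling in a range (matching a simulation retention policy).
#' @return Log density (finite for valid inputs).
#' @export
bds_log_density <- function(tree, params, condition = "survival") {
  if (is.character(condition)) condition <- match.arg(condition, c("survival", "none"))
  stopifnot(inherits(tree, "timetree"), inherits(params, "bds_params"))
  if (abs(params$origin_time - tree$t_s) > 1e-9)
    stop("params$origin_time must equal the tree's sampling time t_s",
         call. = FALSE)
  ages <- internal_ages(tree)
  bds_log_density_ages(ages, params$birth_rate, params$death_rate,
                       params$sampling_proportion, params$origin_time,
                       condition = condition)
}

# Ages (before sampling) of the n-1 binary internal nodes, MRCA included;
# degree-2 subdivision nodes are ignored.
internal_ages <- function(tree) {
  nc <- tabulate(tree$parent[!is.na(tree$parent)], nbins = n_nodes(tree))
  tree$t_s - tree$time[nc == 2L]
}

#' Expected number of sampled cells
#'
#' Closed-form mean tip count of the birth-death-sampling process:
#' \code{rho * exp((lambda - delta) * origin_time)}. Used as a simulator
#' sanity oracle.
#'
#' @param params A \code{\link{bds_params}}.
#' @return Expected sampled tip count.
#' @export
expected_tip_count <- function(params) {
  params$sampling_proportion *
    exp((params$birth_rate - params$death_rate) * params$origin_time)
}
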