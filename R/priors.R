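#' Prior distributions for model parameters
#'
#' Lightweight prior objects used both to draw simulation truths (calibrated
#' studies) and as MCMC priors. A \code{prior_fixed} value flags the
#' parameter as known: it is excluded from sampling and its value is used
#' directly (e.g. "relative scarring rates known" analyses). All supplied
#' distributions are proper.
#'
#' @param meanlog,sdlog,rate,min,max,shape,shape1,shape2,value,mean,sd
#'   Distribution hyperparameters (as in the corresponding stats functions).
#' @return An object of class \code{prior}.
#' @rdname priors
#' @export
prior_lognormal <- function(meanlog = 0, sdlog = 1)
  new_prior("lognormal", list(meanlog = meanlog, sdlog = sdlog))

#' @rdname priors
#' @export
prior_exponential <- function(rate = 1) new_prior("exponential", list(rate = rate))

#' @rdname priors
#' @export
prior_uniform <- function(min = 0, max = 1) {
  stopifnot(max > min)
  new_prior("uniform", list(min = min, max = max))
}

#' @rdname priors
#' @export
prior_gamma <- function(shape = 1, rate = 1)
  new_prior("gamma", list(shape = shape, rate = rate))

#' @rdname priors
#' @export
prior_beta <- function(shape1 = 1, shape2 = 1)
  new_prior("beta", list(shape1 = shape1, shape2 = shape2))

#' @rdname priors
#' @export
prior_normal <- function(mean = 0, sd = 1) new_prior("normal", list(mean = mean, sd = sd))

#' @rdname priors
#' @export
prior_fixed <- function(value) new_prior("fixed", list(value = value))

new_prior <- function(dist, pars) structure(list(dist = dist, pars = pars),
                                            class = "prior")

#' @export
print.prior <- function(x, ...) {
  cat(sprintf("<prior> %s(%s)\n", x$dist,
              paste(names(x$pars), unlist(x$pars), sep = " = ", collapse = ", ")))
  invisible(x)
}

is_fixed_prior <- function(p) inherits(p, "prior") && p$dist == "fixed"

#' Sample from / evaluate a prior
#'
#' @param p A \code{prior}.
#' @param n Number of draws.
#' @param x Values at which to evaluate the density.
#' @param log Return log density.
#' @rdname prior-eval
#' @export
prior_sample <- function(p, n = 1) {
  with(p$pars, switch(p$dist,
    lognormal = rlnorm(n, meanlog, sdlog),
    exponential = rexp(n, rate),
    uniform = runif(n, min, max),
    gamma = rgamma(n, shape, rate),
    beta = rbeta(n, shape1, shape2),
    normal = rnorm(n, mean, sd),
    fixed = rep(value, n)))
}

#' @rdname prior-eval
#' @export
prior_density <- function(p, x, log = TRUE) {
  with(p$pars, switch(p$dist,
    lognormal = dlnorm(x, meanlog, sdlog, log = log),
    exponential = dexp(x, rate, log = log),
    uniform = dunif(x, min, max, log = log),
    gamma = dgamma(x, shape, rate, log = log),
    beta = dbeta(x, shape1, shape2, log = log),
    normal = dnorm(x, mean, sd, log = log),
    fixed = {
      d <- as.numeric(abs(x - value) < 1e-12)
      if (log) log(d) else d
    }))
}

# Quantile function; used for prior-recovery KS tests and prior medians.
prior_quantile <- function(p, q) {
  with(p$pars, switch(p$dist,
    lognormal = stats::qlnorm(q, meanlog, sdlog),
    exponential = stats::qexp(q, rate),
    uniform = stats::qunif(q, min, max),
    gamma = stats::qgamma(q, shape, rate),
    beta = stats::qbeta(q, shape1, shape2),
    normal = stats::qnorm(q, mean, sd),
    fixed = rep(value, length(q))))
}

prior_cdf_fun <- function(p) {
  with(p$pars, switch(p$dist,
    lognormal = function(x) stats::plnorm(x, meanlog, sdlog),
    exponential = function(x) stats::pexp(x, rate),
    uniform = function(x) stats::punif(x, min, max),
    gamma = function(x) stats::pgamma(x, shape, rate),
    beta = function(x) stats::pbeta(x, shape1, shape2),
    normal = function(x) stats::pnorm(x, mean, sd),
    stop("no cdf for this prior", call. = FALSE)))
}

#' Prior specification for the joint model
#'
#' Bundles per-parameter priors for the editing model (edit rate \code{r},
#' silencing rate \code{l}, free scarring multipliers \code{s}) and the
#' birth-death-sampling tree prior (\code{lambda}, \code{delta},
#' \code{rho}). The multiplier prior \code{s} applies independently to each
#' free multiplier s_1..s_(S-1); s_S is fixed at 1 (multiplier
#' parameterization). Use \code{prior_fixed()} to pin a parameter.
#'
#' @param r,l,lambda,delta,rho,s \code{prior} objects.
#' @return An object of class \code{prior_spec}.
#' @export
prior_spec <- function(r = prior_lognormal(log(0.05), 0.5),
                       l = prior_fixed(0),
                       lambda = prior_lognormal(log(0.1), 0.4),
                       delta = prior_fixed(0),
                       rho = prior_uniform(0.01, 1),
                       s = prior_fixed(1)) {
  out <- list(r = r, l = l, lambda = lambda, delta = delta, rho = rho, s = s)
  stopifnot(all(vapply(out, inherits, logical(1), "prior")))
  structure(out, class = c("prior_spec", "list"))
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>\n")
  for (nm in names(x)) { cat(" ", nm, ": "); print(x[[nm]]) }
  invisible(x)
}

# Expand a prior_spec into per-parameter priors for S scar states:
# names r, l, lambda, delta, rho, s_1..s_{S-1}.
expand_priors <- function(priors, S) {
  out <- priors[c("r", "l", "lambda", "delta", "rho")]
  if (S > 1) for (i in seq_len(S - 1)) out[[paste0("s_", i)]] <- priors$s
  out
}

# One truth draw from the priors (named vector).
sample_prior_point <- function(priors, S) {
  ps <- expand_priors(priors, S)
  vapply(ps, prior_sample, numeric(1))
}

# Multiplier vector (length S, last = 1) from a named parameter vector.
multipliers_from_params <- function(par, S) {
  if (S == 1) return(1)
  c(unname(par[paste0("s_", seq_len(S - 1))]), 1)
}
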