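#' Time-dependent editing (scarring/silencing) substitution model
#'
#' Constructs the continuous-time Markov model for a single integration
#' (barcode + target region) of a genetic lineage recorder. The state space is
#' \code{0 = unedited}, \code{1 = silenced}, \code{2..S+1 = scar outcomes
#' 1..S}. Scarring moves an unedited target to scar state \code{i} at rate
#' \code{r * s_i}, but only while the editing enzyme is active, i.e. during
#' the scarring window \code{[window_start, window_end]}. Silencing moves any
#' non-silenced state to the absorbing silenced state at constant rate
#' \code{l} throughout the experiment. Both processes are irreversible.
#'
#' Two parameterizations are supported. Under \code{"multiplier"} the last
#' multiplier is fixed to 1 (\code{s_S = 1}) and \code{edit_rate} is the rate
#' at which scar state S arises, so the \code{s_i} are relative rates. Under
#' \code{"clock"} the multipliers sum to 1 and \code{edit_rate} is the total
#' rate of any edit occurring (a molecular-clock rate). The two are related
#' by \code{r_clock = r_mult * sum(s_mult)} with renormalized multipliers and
#' yield identical transition probabilities.
#'
#' @param edit_rate Non-negative editing rate r, per unit time.
#' @param scarring_multipliers Numeric vector of S non-negative relative
#'   rates, one per distinguishable scar outcome.
#' @param silencing_rate Non-negative silencing rate l, per unit time.
#' @param window_start,window_end Scarring window \code{[t1, t2]}, in forward
#'   time from the experiment start at 0; \code{t1 <= t2}.
#' @param parameterization \code{"multiplier"} (default) or \code{"clock"}.
#' @return An object of class \code{editing_model}.
#' @examples
#' mod <- editing_model(edit_rate = 0.05, scarring_multipliers = c(3, 1),
#'                      window_start = 0, window_end = 16)
#' transition_probabilities(mod, 0, 16)
#' @export
editing_model <- function(edit_rate,
                          scarring_multipliers,
                          silencing_rate = 0,
                          window_start = 0,
                          window_end,
                          parameterization = c("multiplier", "clock")) {
  parameterization <- match.arg(parameterization)
  stopifnot(is.numeric(edit_rate), length(edit_rate) == 1L,
            is.numeric(scarring_multipliers), length(scarring_multipliers) >= 1L,
            is.numeric(silencing_rate), length(silencing_rate) == 1L)
  if (edit_rate < 0 || silencing_rate < 0 || any(scarring_multipliers < 0))
    stop("all rates must be non-negative", call. = FALSE)
  if (window_start < 0 || window_end < window_start)
    stop("scarring window requires 0 <= window_start <= window_end", call. = FALSE)
  S <- length(scarring_multipliers)
  if (parameterization == "multiplier") {
    if (abs(scarring_multipliers[S] - 1) > 1e-12)
      stop("multiplier parameterization fixes the last scarring multiplier to 1",
           call. = FALSE)
  } else {
    if (abs(sum(scarring_multipliers) - 1) > 1e-12)
      stop("clock parameterization requires scarring multipliers summing to 1",
           call. = FALSE)
  }
  structure(
    list(scar_count = S,
         scarring_multipliers = as.numeric(scarring_multipliers),
         edit_rate = as.numeric(edit_rate),
         silencing_rate = as.numeric(silencing_rate),
         window_start = as.numeric(window_start),
         window_end = as.numeric(window_end),
         parameterization = parameterization),
    class = "editing_model")
}

#' @export
print.editing_model <- function(x, ...) {
  cat(sprintf("<editing_model> S = %d scar states, %s parameterization\n",
              x$scar_count, x$parameterization))
  cat(sprintf("  edit rate r = %g, silencing rate l = %g\n",
              x$edit_rate, x$silencing_rate))
  cat(sprintf("  scarring window [%g, %g], multipliers: %s\n",
              x$window_start, x$window_end,
              paste(signif(x$scarring_multipliers, 4), collapse = ", ")))
  invisible(x)
}

#' Convert between multiplier and clock parameterizations
#'
#' @param model An \code{editing_model}.
#' @return An equivalent \code{editing_model} in the requested
#'   parameterization (identical transition probabilities).
#' @rdname reparameterize
#' @export
as_clock_model <- function(model) {
  stopifnot(inherits(model, "editing_model"))
  if (model$parameterization == "clock") return(model)
  sigma <- sum(model$scarring_multipliers)
  if (sigma == 0)
    stop("cannot renormalize all-zero scarring multipliers", call. = FALSE)
  editing_model(edit_rate = model$edit_rate * sigma,
                scarring_multipliers = model$scarring_multipliers / sigma,
                silencing_rate = model$silencing_rate,
                window_start = model$window_start,
                window_end = model$window_end,
                parameterization = "clock")
}

#' @rdname reparameterize
#' @export
as_multiplier_model <- function(model) {
  stopifnot(inherits(model, "editing_model"))
  if (model$parameterization == "multiplier") return(model)
  S <- model$scar_count
  sS <- model$scarring_multipliers[S]
  if (sS == 0)
    stop("last scarring multiplier is zero; cannot rescale to multiplier form",
         call. = FALSE)
  editing_model(edit_rate = model$edit_rate * sS,
                scarring_multipliers = model$scarring_multipliers / sS,
                silencing_rate = model$silencing_rate,
                window_start = model$window_start,
                window_end = model$window_end,
                parameterization = "multiplier")
}

#' Instantaneous rate matrix of the editing model
#'
#' Returns the (S+2) x (S+2) generator at time point \code{time}: inside the
#' scarring window the unedited state flows to each scar state i at rate
#' \code{r * s_i} and to silenced at rate l; outside the window only
#' silencing is active. Scar states can only be silenced; silenced is
#' absorbing. Rows/columns are ordered unedited, silenced, scar_1..scar_S.
#'
#' @param model An \code{editing_model}.
#' @param time Non-negative time point (forward from experiment start).
#' @return Square numeric matrix with zero row sums.
#' @export
rate_matrix <- function(model, time) {
  stopifnot(inherits(model, "editing_model"), is.numeric(time), length(time) == 1L)
  if (time < 0) stop("time must be non-negative", call. = FALSE)
  S <- model$scar_count
  k <- S + 2L
  l <- model$silencing_rate
  Q <- matrix(0, k, k)
  in_window <- time >= model$window_start && time <= model$window_end
  scar_rates <- if (in_window) model$edit_rate * model$scarring_multipliers else numeric(S)
  Q[1, 1] <- -(l + sum(scar_rates))
  Q[1, 2] <- l
  Q[1, 2L + seq_len(S)] <- scar_rates
  for (i in seq_len(S)) {
    Q[2L + i, 2L] <- l
    Q[2L + i, 2L + i] <- -l
  }
  Q
}

#' Closed-form transition probabilities over a window-homogeneous interval
#'
#' Computes P(start -> end) analytically in O(S), without matrix
#' exponentiation. The interval must lie entirely inside or entirely outside
#' the scarring window (use \code{\link{propagate_across_window}} for
#' arbitrary intervals). Writing d = end - start and sigma = sum(s_i), the
#' in-window forms are P(0->0) = exp(-(l + r*sigma) d), P(0->scar_i) =
#' (s_i/sigma) exp(-l d) (1 - exp(-r sigma d)), P(scar_i->scar_i) =
#' exp(-l d), with all remaining mass silenced; out of window the scarring
#' terms vanish.
#'
#' @param model An \code{editing_model}.
#' @param start_time,end_time Interval bounds, \code{0 <= start <= end}, not
#'   straddling \code{window_start} or \code{window_end}.
#' @return Row-stochastic (S+2) x (S+2) matrix.
#' @export
transition_probabilities <- function(model, start_time, end_time) {
  stopifnot(inherits(model, "editing_model"))
  if (start_time < 0 || end_time < start_time)
    stop("need 0 <= start_time <= end_time", call. = FALSE)
  t1 <- model$window_start; t2 <- model$window_end
  inside  <- start_time >= t1 && end_time <= t2
  outside <- end_time <= t1 || start_time >= t2
  if (!inside && !outside)
    stop("interval straddles a scarring-window boundary; subdivide first",
         call. = FALSE)
  d <- end_time - start_time
  S <- model$scar_count
  k <- S + 2L
  l <- model$silencing_rate
  P <- matrix(0, k, k)
  surv_l <- exp(-l * d)            # probability of escaping silencing
  sil    <- -expm1(-l * d)         # 1 - exp(-l d), cancellation-safe
  P[2, 2] <- 1                     # silenced is absorbing
  for (i in seq_len(S)) {
    P[2L + i, 2L + i] <- surv_l
    P[2L + i, 2L] <- sil
  }
  if (inside && d > 0) {
    s <- model$scarring_multipliers
    sigma <- sum(s)
    rs <- model$edit_rate * sigma
    P[1, 1] <- exp(-(l + rs) * d)
    if (sigma > 0)
      P[1, 2L + seq_len(S)] <- (s / sigma) * surv_l * (-expm1(-rs * d))
    P[1, 2] <- sil                 # total silencing mass from unedited
  } else {
    P[1, 1] <- surv_l
    P[1, 2] <- sil
  }
  P
}

#' Transition probabilities over an arbitrary interval
#'
#' Splits \code{[start_time, end_time]} at the scarring-window boundaries t1
#' and t2 into at most three window-homogeneous segments and returns the
#' ordered product of their closed-form transition matrices.
#'
#' @inheritParams transition_probabilities
#' @return Row-stochastic (S+2) x (S+2) matrix.
#' @export
propagate_across_window <- function(model, start_time, end_time) {
  stopifnot(inherits(model, "editing_model"))
  if (start_time < 0 || end_time < start_time)
    stop("need 0 <= start_time <= end_time", call. = FALSE)
  cuts <- sort(unique(c(start_time,
                        pmin(pmax(c(model$window_start, model$window_end),
                                  start_time), end_time),
                        end_time)))
  P <- diag(model$scar_count + 2L)
  for (i in seq_len(length(cuts) - 1L))
    P <- P %*% transition_probabilities(model, cuts[i], cuts[i + 1L])
  P
}

#' Per-site editing models with parameter sharing across targets
#'
#' Bundles m per-target editing models that share the scarring window.
#' Sharing modes mirror common analysis settings: \code{"shared_all"} uses
#' one model for every site; \code{"shared_edit_rate"} shares the editing
#' rate r but lets each site keep its own outcome multipliers;
#' \code{"free"} gives every site its own rate and multipliers.
#'
#' @param models A single \code{editing_model} (recycled to m sites) or a
#'   list of m of them.
#' @param n_sites Number of targets m (required when \code{models} is a
#'   single model).
#' @param sharing One of \code{"shared_all"}, \code{"shared_edit_rate"},
#'   \code{"free"}.
#' @return An object of class \code{site_models}.
#' @export
site_models <- function(models, n_sites = NULL,
                        sharing = c("shared_all", "shared_edit_rate", "free")) {
  sharing <- match.arg(sharing)
  if (inherits(models, "editing_model")) {
    if (is.null(n_sites)) stop("n_sites required with a single model", call. = FALSE)
    models <- rep(list(models), n_sites)
  }
  stopifnot(is.list(models), length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "editing_model")))
  if (length(unique(vapply(models, `[[`, integer(1), "scar_count"))) != 1L)
    stop("all per-site models must share the scar-state space (equal S)",
         call. = FALSE)
  t1 <- vapply(models, `[[`, numeric(1), "window_start")
  t2 <- vapply(models, `[[`, numeric(1), "window_end")
  if (max(t1) - min(t1) > 1e-12 || max(t2) - min(t2) > 1e-12)
    stop("all per-site models must share the scarring window", call. = FALSE)
  r <- vapply(models, `[[`, numeric(1), "edit_rate")
  if (sharing == "shared_all") {
    same <- all(vapply(models[-1], function(mm)
      isTRUE(all.equal(mm[-match("parameterization", names(mm))],
                       models[[1]][-match("parameterization", names(models[[1]]))])),
      logical(1)))
    if (!same) stop("shared_all requires identical per-site models", call. = FALSE)
  } else if (sharing == "shared_edit_rate") {
    if (max(r) - min(r) > 1e-12)
      stop("shared_edit_rate requires one edit rate across sites", call. = FALSE)
  }
  structure(list(models = models, sharing = sharing,
                 n_sites = length(models)), class = "site_models")
}

#' @export
print.site_models <- function(x, ...) {
  cat(sprintf("<site_models> m = %d targets, sharing = %s\n", x$n_sites, x$sharing))
  print(x$models[[1]])
  invisible(x)
}

# Coerce a model spec to site_models, recycling a single editing_model.
as_site_models <- function(model, n_sites) {
  if (inherits(model, "site_models")) {
    if (model$n_sites != n_sites)
      stop(sprintf("model has %d sites but data has %d targets",
                   model$n_sites, n_sites), call. = FALSE)
    model
  } else if (inherits(model, "editing_model")) {
    site_models(model, n_sites = n_sites, sharing = "shared_all")
  } else stop("model must be an editing_model or site_models", call. = FALSE)
}

#' Serialize an editing model to / from JSON-ready lists
#'
#' @param model An \code{editing_model}.
#' @param x A list with keys \code{edit_rate}, \code{scarring_multipliers},
#'   \code{silencing_rate}, \code{window_start}, \code{window_end},
#'   \code{parameterization} (e.g. parsed from JSON).
#' @return \code{editing_model_to_list}: a plain list; \code{editing_model_from_list}:
#'   an \code{editing_model}.
#' @rdname editing-model-json
#' @export
editing_model_to_list <- function(model) {
  stopifnot(inherits(model, "editing_model"))
  model[c("edit_rate", "scarring_multipliers", "silencing_rate",
          "window_start", "window_end", "parameterization")]
}

#' @rdname editing-model-json
#' @export
editing_model_from_list <- function(x) {
  needed <- c("edit_rate", "scarring_multipliers", "window_end")
  if (!all(needed %in% names(x)))
    stop("missing keys: ", paste(setdiff(needed, names(x)), collapse = ", "),
         call. = FALSE)
  editing_model(edit_rate = x$edit_rate,
                scarring_multipliers = unlist(x$scarring_multipliers),
                silencing_rate = x$silencing_rate %||% 0,
                window_start = x$window_start %||% 0,
                window_end = x$window_end,
                parameterization = x$parameterization %||% "multiplier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
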