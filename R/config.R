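#' Run configuration: JSON schema, validation and defaults
#'
#' A run configuration bundles everything needed to reproduce a simulation
#' or inference run: the editing model, birth-death-sampling parameters,
#' simulator settings, priors and MCMC chain settings, plus a seed and an
#' output directory. \code{validate_config()} checks a parsed JSON config
#' (or file) against the schema, rejects unknown keys (typo safety),
#' enumerates all problems at once, and fills defaults.
#'
#' @param x A file path to a JSON config or an already-parsed list.
#' @return A validated \code{run_config} list with defaults filled.
#' @export
validate_config <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  stopifnot(is.list(x))
  errors <- character(0)
  note <- function(...) errors <<- c(errors, sprintf(...))

  defaults <- list(
    schema_version = 1L, seed = 1L, out_dir = ".",
    model = list(edit_rate = 0.05, scarring_multipliers = c(1, 1),
                 silencing_rate = 0, window_start = 0, window_end = 16,
                 parameterization = "multiplier"),
    bds = list(birth_rate = 0.15, death_rate = 0, sampling_proportion = 0.5,
               origin_time = 32),
    simulate = list(n_targets = 20, dropout_prob = 0, n_replicates = 1,
                    min_tips = 2, max_tips = 1e9),
    priors = list(),
    inference = list(n_iter = 20000, burnin = 0.1, thin = NA,
                     pooling = "shared_params", t_s = 32,
                     silenced_is_missing = FALSE, condition = "survival"),
    metrics = list(t2 = 16, level = 0.95,
                   parameters = c("tree_height", "tree_length",
                                  "lambda", "rho")))
  known_prior_keys <- c("r", "l", "lambda", "delta", "rho", "s")

  unknown <- setdiff(names(x), names(defaults))
  for (k in unknown) note("unknown top-level key: '%s'", k)
  for (section in intersect(names(x), names(defaults))) {
    if (section %in% c("schema_version", "seed", "out_dir")) next
    if (!is.list(x[[section]])) { note("'%s' must be an object", section); next }
    bad <- setdiff(names(x[[section]]),
                   if (section == "priors") known_prior_keys
                   else names(defaults[[section]]))
    for (k in bad) note("unknown key: '%s.%s'", section, k)
  }
  cfg <- utils::modifyList(defaults, x[intersect(names(x), names(defaults))])

  chk_pos <- function(path, v, allow_zero = TRUE) {
    if (!is.numeric(v) || length(v) < 1 || any(v < 0) ||
        (!allow_zero && any(v == 0)))
      note("'%s' must be %s", path,
           if (allow_zero) "a non-negative number" else "a positive number")
  }
  chk_pos("model.edit_rate", cfg$model$edit_rate)
  chk_pos("model.silencing_rate", cfg$model$silencing_rate)
  chk_pos("model.scarring_multipliers", cfg$model$scarring_multipliers)
  chk_pos("bds.birth_rate", cfg$bds$birth_rate)
  chk_pos("bds.death_rate", cfg$bds$death_rate)
  chk_pos("bds.origin_time", cfg$bds$origin_time, allow_zero = FALSE)
  if (!is.numeric(cfg$bds$sampling_proportion) ||
      cfg$bds$sampling_proportion <= 0 || cfg$bds$sampling_proportion > 1)
    note("'bds.sampling_proportion' must be in (0, 1]")
  if (is.numeric(cfg$model$window_start) && is.numeric(cfg$model$window_end) &&
      cfg$model$window_end < cfg$model$window_start)
    note("'model.window_end' must be >= 'model.window_start'")
  if (length(errors))
    stop("invalid run configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  cfg$model <- editing_model_to_list(editing_model_from_list(cfg$model))
  structure(cfg, class = c("run_config", "list"))
}

#' Write the resolved configuration for provenance
#'
#' @param cfg A \code{run_config}.
#' @param path Output JSON path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Priors from / to plain lists
#'
#' @param x Named list of \code{{dist = ..., <hyperparameters>}} entries for
#'   any of r, l, lambda, delta, rho, s (missing entries keep
#'   \code{prior_spec()} defaults).
#' @return A \code{prior_spec}.
#' @export
priors_from_list <- function(x) {
  conv <- function(p) {
    d <- p$dist %||% stop("prior entry needs a 'dist'", call. = FALSE)
    pars <- p[setdiff(names(p), "dist")]
    do.call(switch(d,
                   lognormal = prior_lognormal, exponential = prior_exponential,
                   uniform = prior_uniform, gamma = prior_gamma,
                   beta = prior_beta, normal = prior_normal,
                   fixed = prior_fixed,
                   stop("unknown prior distribution: ", d, call. = FALSE)),
            pars)
  }
  do.call(prior_spec, lapply(x, conv))
}

#' Built-in worked fixtures
#'
#' Deterministically regenerates small example datasets used in the
#' documentation and tests: \code{"worked4"} is a 4-cell, 5-target dataset
#' on a hand-checkable tree; \code{"calibrated20"} is a 20-replicate
#' calibrated-study bundle (truths drawn from the default priors).
#'
#' @param name \code{"worked4"} or \code{"calibrated20"}.
#' @param dir Output directory (created); when NULL the objects are
#'   returned without writing.
#' @return Invisibly (written to \code{dir}) or directly: a list of fixture
#'   objects.
#' @export
fixture <- function(name = c("worked4", "calibrated20"), dir = NULL) {
  name <- match.arg(name)
  out <- switch(name,
    worked4 = {
      tree <- parse_newick("((cell_1:22,cell_2:22):6,(cell_3:10,cell_4:10):18):0;",
                           origin_height = 32)
      model <- editing_model(0.05, c(3, 1), window_start = 0, window_end = 16)
      tab <- simulate_barcodes(tree, model, n_targets = 5, seed = 42)
      list(tree = tree, model = model, table = tab, t_s = 32)
    },
    calibrated20 = {
      pr <- prior_spec(r = prior_lognormal(log(0.05), 0.4),
                       lambda = prior_lognormal(log(0.08), 0.25),
                       rho = prior_uniform(0.1, 0.8),
                       s = prior_fixed(3))
      run_calibrated_study(pr, 20,
                           template = list(n_targets = 20, min_tips = 3,
                                           max_tips = 30),
                           seed = 2024)
    })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (name == "worked4") {
      write_newick(out$tree, file.path(dir, "tree.newick"))
      write_edit_table(out$table, file.path(dir, "table.tsv"))
      jsonlite::write_json(editing_model_to_list(out$model),
                           file.path(dir, "model.json"), auto_unbox = TRUE,
                           digits = NA)
    } else {
      readr::write_tsv(out$truths, file.path(dir, "truths.tsv"))
      for (i in seq_along(out$datasets)) {
        d <- file.path(dir, sprintf("rep_%02d", i))
        dir.create(d, showWarnings = FALSE)
        write_newick(out$datasets[[i]]$tree, file.path(d, "tree.newick"))
        write_edit_table(out$datasets[[i]]$table, file.path(d, "table.tsv"))
      }
    }
  }
  invisible(out)
}
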