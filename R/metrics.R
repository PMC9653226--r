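#' Parameter-recovery scoreboard across simulated replicates
#'
#' Given per-replicate truths and fitted chains, extracts posterior medians
#' and 95% HPD intervals for the tracked parameters and computes, per
#' parameter and per phylogenetic-signal stratum: coverage of the HPD
#' interval (%), bias (mean of median - truth), RMSE, mean HPD width, and
#' Pearson correlation between medians and truths with a Fisher-z 95% CI.
#' Replicates are stratified by whether the true MRCA falls inside the
#' editing window (\code{mrca_time <= t2}: phylogenetic signal) or after it.
#'
#' @param truths Tibble with one row per replicate, containing a
#'   \code{replicate} column, a column per tracked parameter (e.g.
#'   \code{lambda}, \code{rho}, \code{tree_height}, \code{tree_length}) and
#'   \code{mrca_time}.
#' @param fits List of \code{scartree_fit}, aligned with \code{truths} rows.
#' @param t2 Editing-window end used for stratification.
#' @param parameters Tracked parameter names; tree height/length map to the
#'   first dataset's \code{tree_height_1}/\code{tree_length_1} trace columns.
#' @param level Credible level (default 0.95).
#' @return A \code{recovery_report}: list with \code{estimates} (one row per
#'   replicate x parameter: truth, median, lower, upper, signal) and
#'   \code{summary}; \code{tidy()} returns the summary.
#' @export
recovery_report <- function(truths, fits, t2,
                            parameters = c("tree_height", "tree_length",
                                           "lambda", "rho"),
                            level = 0.95) {
  stopifnot(nrow(truths) == length(fits))
  est <- purrr::map_dfr(seq_len(nrow(truths)), function(i) {
    sm <- summarize_posterior(fits[[i]], level = level)
    purrr::map_dfr(parameters, function(pn) {
      col <- if (pn %in% c("tree_height", "tree_length"))
        paste0(pn, "_1") else pn
      row <- sm[sm$parameter == col, ]
      if (nrow(row) == 0)
        stop(sprintf("parameter '%s' not found in fit %d", col, i),
             call. = FALSE)
      tibble::tibble(replicate = truths$replicate[i], parameter = pn,
                     truth = truths[[pn]][i], median = row$median,
                     lower = row$lower, upper = row$upper,
                     mrca_time = truths$mrca_time[i])
    })
  })
  recovery_report_from_estimates(est, t2)
}

#' Recovery report from a prebuilt estimates table
#'
#' @param estimates Tibble with columns replicate, parameter, truth, median,
#'   lower, upper and (optionally) mrca_time.
#' @param t2 Editing-window end (signal stratification); when
#'   \code{mrca_time} is absent all replicates fall in one stratum.
#' @return A \code{recovery_report}.
#' @export
recovery_report_from_estimates <- function(estimates, t2 = Inf) {
  est <- tibble::as_tibble(estimates)
  est$signal <- if ("mrca_time" %in% names(est))
    ifelse(est$mrca_time <= t2, "signal", "no_signal") else "signal"
  summ <- est |>
    dplyr::group_by(.data$parameter, .data$signal) |>
    dplyr::summarise(
      n = dplyr::n(),
      coverage = 100 * mean(.data$truth >= .data$lower &
                            .data$truth <= .data$upper),
      bias = mean(.data$median - .data$truth),
      rmse = sqrt(mean((.data$median - .data$truth)^2)),
      mean_hpd_width = mean(.data$upper - .data$lower),
      .groups = "drop")
  cors <- est |>
    dplyr::group_by(.data$parameter, .data$signal) |>
    dplyr::group_modify(~ pearson_ci(.x$median, .x$truth)) |>
    dplyr::ungroup()
  summ <- dplyr::left_join(summ, cors, by = c("parameter", "signal"))
  structure(list(estimates = est, summary = summ, t2 = t2),
            class = "recovery_report")
}

# Pearson R with Fisher-z 95% CI; undefined (NA + flag) below 3 pairs or at
# zero variance.
pearson_ci <- function(x, y) {
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
    return(tibble::tibble(pearson_r = NA_real_, r_lower = NA_real_,
                          r_upper = NA_real_, r_undefined = TRUE))
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  tibble::tibble(pearson_r = unname(ct$estimate),
                 r_lower = ct$conf.int[1], r_upper = ct$conf.int[2],
                 r_undefined = FALSE)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates, %d parameters\n",
              length(unique(x$estimates$replicate)),
              length(unique(x$estimates$parameter))))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.recovery_report <- function(x, ...) x$summary

#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(n_replicates = length(unique(x$estimates$replicate)),
                 n_parameters = length(unique(x$estimates$parameter)),
                 n_signal = sum(x$estimates$signal == "signal") /
                   max(1, length(unique(x$estimates$parameter))))
}

#' Robinson-Foulds distance between two timetrees
#'
#' Symmetric difference of the nontrivial (unrooted) bipartitions.
#'
#' @param a,b \code{timetree}s on the same tip-label set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(a, b) {
  pa <- as.phylo.timetree(a); pb <- as.phylo.timetree(b)
  if (!setequal(pa$tip.label, pb$tip.label))
    stop("trees must share the same tip labels", call. = FALSE)
  as.integer(phangorn::RF.dist(ape::unroot(pa), ape::unroot(pb)))
}

#' Triplet distance between two rooted timetrees
#'
#' Number of tip triples {a, b, c} whose rooted resolution (which pair is
#' the cherry) differs between the two trees; bounded by C(n, 3).
#'
#' @param a,b \code{timetree}s on the same tip-label set.
#' @return Integer triplet distance.
#' @export
triplet_distance <- function(a, b) {
  labs <- sort(a$label[tree_tips(a)])
  if (!setequal(labs, b$label[tree_tips(b)]))
    stop("trees must share the same tip labels", call. = FALSE)
  Ma <- mrca_time_matrix(a, labs)
  Mb <- mrca_time_matrix(b, labs)
  n <- length(labs)
  d <- 0L
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ra <- triple_resolution(Ma[i, j], Ma[i, k], Ma[j, k])
    rb <- triple_resolution(Mb[i, j], Mb[i, k], Mb[j, k])
    if (ra != rb) d <- d + 1L
  }
  d
}

# Which pair is the cherry: 1 = (i,j), 2 = (i,k), 3 = (j,k), 0 = unresolved.
# The cherry pair has the strictly most recent (largest-time) MRCA.
triple_resolution <- function(tij, tik, tjk) {
  ts <- c(tij, tik, tjk)
  mx <- max(ts)
  w <- which(ts > mx - 1e-9)
  if (length(w) == 1L) w else 0L
}

# Pairwise MRCA node-time matrix over the given ordered labels.
mrca_time_matrix <- function(tree, labs) {
  kids <- tree_children(tree)
  tips <- tree_tips(tree)
  idx <- match(tree$label[tips], labs)
  n <- length(labs)
  M <- matrix(NA_real_, n, n)
  below <- vector("list", n_nodes(tree))
  for (nd in order(tree$time, decreasing = TRUE)) {
    if (nd %in% tips) { below[[nd]] <- idx[match(nd, tips)]; next }
    ch <- kids[[nd]]
    if (length(ch) == 1L) { below[[nd]] <- below[[ch]]; next }
    A <- below[[ch[1]]]; B <- below[[ch[2]]]
    for (x in A) for (y in B) { M[x, y] <- M[y, x] <- tree$time[nd] }
    below[[nd]] <- c(A, B)
  }
  M
}
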