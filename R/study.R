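# Monte Carlo harness: replications, aggregation into Type I error and
# power, and Bradley's liberal accuracy criterion.

#' Bradley's liberal accuracy criterion
#'
#' An empirical Type I error rate is considered accurate for nominal
#' level 0.05 when it lies in the closed interval [0.025, 0.075].
#'
#' @param rate Proportion(s) in `[0, 1]`.
#' @return Logical vector.
#' @export
bradley_accurate <- function(rate) {
  if (any(rate < 0 | rate > 1, na.rm = TRUE))
    stop_with("dinadif_invalid", "`rate` must lie in [0, 1]")
  rate >= 0.025 & rate <= 0.075
}

#' Run one simulation replication
#'
#' Simulates a data set under `cond`, fits the DINA model in both
#' groups, and applies every requested DIF method to every item.  A
#' replication counts as converged only when both EM fits converged and
#' every (item, method) decision is testable; any failure (including a
#' singular covariance) marks the whole replication non-converged so the
#' methods stay comparable on identical data.
#'
#' @param cond A [dif_condition()].
#' @param seed Integer replication seed.
#' @param methods Methods to run (see [dif_test()]).
#' @return List with `seed`, `converged`, the `dif_test` `results`
#'   data frame (or `NULL` on hard failure), and the condition's DIF
#'   item indices.
#' @export
run_replication <- function(cond, seed,
                            methods = c("Wd", "WXPD", "WObs", "WSw", "MH", "LR")) {
  stopifnot(inherits(cond, "dif_condition"))
  dat <- sim_dif_data(cond, seed)
  scan <- tryCatch(
    dif_test(dat$x, dat$group, cond$q, methods = methods, alpha = cond$alpha),
    dinadif_error = function(e) e)
  if (inherits(scan, "condition"))
    return(list(seed = seed, converged = FALSE, results = NULL,
                failure = conditionMessage(scan), dif_items = cond$dif_items))
  fits_ok <- is.null(scan$fits) ||
    (scan$fits$reference$converged && scan$fits$focal$converged)
  ok <- fits_ok && !anyNA(scan$results$p_value)
  list(seed = seed, converged = ok, results = scan$results,
       dif_items = cond$dif_items)
}

#' Aggregate replication results into error and power rates
#'
#' Type I error is the proportion of (non-DIF item, replication) pairs
#' flagged; power is the proportion of (DIF item, replication) pairs
#' flagged, both per method and over converged replications only.
#'
#' @param reps List of converged [run_replication()] results.
#' @param dif_items Indices of the true DIF items.
#' @return Data frame with one row per method: `method`, `type_I_error`,
#'   `power`, `n_replications`, `bradley_accurate`.
#' @export
aggregate_rates <- function(reps, dif_items) {
  reps <- Filter(function(r) isTRUE(r$converged), reps)
  if (length(reps) == 0L)
    stop_with("dinadif_invalid", "no converged replications to aggregate")
  all_res <- do.call(rbind, lapply(reps, `[[`, "results"))
  is_dif <- all_res$item %in% dif_items
  agg <- function(sub) {
    tapply(sub$flagged, sub$method, function(z) mean(z, na.rm = TRUE))
  }
  t1 <- agg(all_res[!is_dif, , drop = FALSE])
  pw <- agg(all_res[is_dif, , drop = FALSE])
  methods <- levels(all_res$method)
  out <- data.frame(method = methods,
                    type_I_error = as.vector(t1[methods]),
                    power = if (any(is_dif)) as.vector(pw[methods]) else NA_real_,
                    n_replications = length(reps))
  out$bradley_accurate <- bradley_accurate(out$type_I_error)
  out
}

#' Run a Monte Carlo study over simulation conditions
#'
#' For each condition, draws replications (with counter-based child
#' seeds of `seed`) until `n_reps` converged ones are collected; failed
#' draws are discarded and replaced without disturbing the seeds of the
#' other replications.  If more than `max_fail_rate` of the attempted
#' draws fail, the condition aborts with diagnostics rather than
#' silently conditioning on convergence.
#'
#' @param conditions A data frame of condition parameters (one row per
#'   condition, columns as in [dif_condition_grid()]), a single
#'   [dif_condition()], or a list of them.
#' @param n_reps Converged replications per condition.
#' @param seed Master seed.
#' @param methods DIF methods to run.
#' @param max_fail_rate Abort threshold for the convergence-failure
#'   share.
#' @param N,alpha Overrides forwarded to [dif_condition()] when
#'   `conditions` is a parameter data frame.
#' @return Object of class `"dif_study"`: a data frame with one row per
#'   condition x method carrying the condition parameters,
#'   `type_I_error`, `power`, `bradley_accurate`, `n_replications` and
#'   `n_failed`.
#' @export
run_study <- function(conditions, n_reps = 50L, seed = 1L,
                      methods = c("Wd", "WXPD", "WObs", "WSw", "MH", "LR"),
                      max_fail_rate = 0.2, N = 1000L, alpha = 0.05) {
  if (inherits(conditions, "dif_condition")) conditions <- list(conditions)
  if (is.data.frame(conditions)) {
    conditions <- lapply(seq_len(nrow(conditions)), function(i) {
      r <- conditions[i, ]
      dif_condition(quality = r$quality, rho = r$rho, pct_dif = r$pct_dif,
                    dif_type = r$dif_type, size = r$size,
                    sign_g = r$sign_g, sign_s = r$sign_s,
                    N = N, alpha = alpha)
    })
  }
  out <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    reps <- vector("list", n_reps)
    got <- 0L; attempt <- 0L; failed <- 0L
    max_attempts <- ceiling(n_reps / (1 - max_fail_rate)) + 2L
    while (got < n_reps) {
      attempt <- attempt + 1L
      if (attempt > max_attempts)
        stop_with("dinadif_invalid",
                  sprintf("condition %d: %d of %d replication draws failed to converge (> %.0f%% allowed)",
                          ci, failed, attempt - 1L, 100 * max_fail_rate))
      rep_seed <- child_seed(seed, ci * 100003L + attempt)
      r <- run_replication(cond, rep_seed, methods = methods)
      if (isTRUE(r$converged)) {
        got <- got + 1L
        reps[[got]] <- r
      } else failed <- failed + 1L
    }
    rates <- aggregate_rates(reps, cond$dif_items)
    rates$n_failed <- failed
    meta <- data.frame(condition = ci, quality = cond$quality, rho = cond$rho,
                       pct_dif = cond$pct_dif, dif_type = cond$dif_type,
                       size = cond$size, sign_g = cond$sign_g,
                       sign_s = cond$sign_s)
    out[[ci]] <- cbind(meta[rep(1L, nrow(rates)), , drop = FALSE], rates)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("dif_study", "data.frame")
  attr(res, "seed") <- seed
  attr(res, "n_reps") <- n_reps
  res
}
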