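# Wald DIF statistics and the combined per-item DIF scan.

#' Contrast matrix for the two-group item DIF hypothesis
#'
#' Contrasts \eqn{(g_F - g_R, s_F - s_R)} out of
#' \eqn{v_j' = (g_F, s_F, g_R, s_R)}; the Wald statistic has 2 degrees
#' of freedom.
#'
#' @return The 2 x 4 matrix `rbind(c(1,0,-1,0), c(0,1,0,-1))`.
#' @export
dif_contrast <- function() {
  rbind(c(1, 0, -1, 0),
        c(0, 1, 0, -1))
}

#' Wald statistic for one item
#'
#' \eqn{W = (Cv)' (C \Sigma C')^{-1} (Cv)} with the contrast of
#' [dif_contrast()], referred to a chi-square distribution with 2
#' degrees of freedom.
#'
#' @param v Length-4 vector \eqn{(g_F, s_F, g_R, s_R)}.
#' @param sigma 4 x 4 covariance block from [item_cov_block()].
#' @return List with `statistic`, `df` (= 2) and `p_value`.
#' @export
wald_stat <- function(v, sigma) {
  if (length(v) != 4L) stop_with("dinadif_invalid", "`v` must have length 4")
  sigma <- as.matrix(sigma)
  C <- dif_contrast()
  d <- drop(C %*% v)
  M <- C %*% sigma %*% t(C)
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-12)
    stop_with("dinadif_singular", "contrast covariance C Sigma C' is singular")
  W <- drop(crossprod(d, solve(M, d)))
  list(statistic = W, df = 2L,
       p_value = pchisq(W, df = 2, lower.tail = FALSE))
}

#' Classify the DIF type of an item
#'
#' Uniform DIF requires \eqn{\Delta_g = g_F - g_R} and
#' \eqn{\Delta_s = s_R - s_F} to be nonzero with the same sign (the
#' focal group is then uniformly advantaged or disadvantaged across all
#' mastery patterns); opposite signs, or exactly one zero delta, give
#' non-uniform DIF; two zero deltas mean no DIF.
#'
#' @param delta_g,delta_s The two parameter differences.
#' @return One of `"none"`, `"uniform"`, `"nonuniform"`.
#' @export
classify_dif_type <- function(delta_g, delta_s) {
  sg <- sign(delta_g); ss <- sign(delta_s)
  if (sg == 0 && ss == 0) return("none")
  if (sg != 0 && ss != 0 && sg == ss) return("uniform")
  "nonuniform"
}

# Per-group covariance cache: compute scores and the finite-difference
# Hessian at most once per group, whatever subset of Wald estimators was
# requested.  Structural parameters of boundary classes are excluded
# before inversion (see free_params); the item blocks are unaffected.
.wald_cov_cache <- function(fit, wald_methods, rcond_tol = 1e-12) {
  idx <- free_params(fit)
  xpd <- if (any(c("WXPD", "WSw") %in% wald_methods))
    info_xpd(dina_scores(fit$x, fit$guess, fit$slip, fit$eta, fit$q))[idx, idx]
  obs <- if (any(c("WObs", "WSw") %in% wald_methods))
    info_obs(fit$x, fit$guess, fit$slip, fit$eta, fit$q)[idx, idx]
  out <- list()
  if ("Wd" %in% wald_methods)
    out$Wd <- itemwise_vcov(fit, rcond_tol)
  if ("WXPD" %in% wald_methods)
    out$WXPD <- info_to_vcov("xpd", xpd = xpd, rcond_tol = rcond_tol)
  if ("WObs" %in% wald_methods)
    out$WObs <- info_to_vcov("obs", obs = obs, rcond_tol = rcond_tol)
  if ("WSw" %in% wald_methods)
    out$WSw <- info_to_vcov("sandwich", xpd = xpd, obs = obs,
                            rcond_tol = rcond_tol)
  out
}

#' Scan every item for DIF
#'
#' Runs any subset of the six detection methods on a two-group response
#' matrix at significance level `alpha`.  The Wald family (`Wd`,
#' `WXPD`, `WObs`, `WSw`) fits the DINA model separately in each group
#' via [dina_groups()], builds the requested covariance estimator once
#' per group, and tests \eqn{H_0: g_F = g_R, s_F = s_R} per item with 2
#' df.  `MH` is the Mantel-Haenszel test stratified on the observed
#' total score and `LR` the 2-df logistic-regression likelihood-ratio
#' test; neither uses the fitted model.
#'
#' Items whose covariance block (or stratified table) is numerically
#' singular are reported with `NA` statistic and flag rather than
#' flagged.
#'
#' @param x N x J binary response matrix, both groups stacked.
#' @param group Group labels (reference/focal, "R"/"F", or 0/1).
#' @param q J x K binary Q-matrix (needed by the Wald methods).
#' @param methods Subset of `c("Wd","WXPD","WObs","WSw","MH","LR")`.
#' @param alpha Significance level for flagging (default 0.05).
#' @param ... Passed to [dina()] (e.g. `tol`, `max_iter`).
#' @return Object of class `"dina_dif"`: a list with a `results` data
#'   frame (`item`, `method`, `statistic`, `df`, `p_value`, `flagged`),
#'   the per-group fits (when computed), the estimated parameter
#'   differences, and `alpha`.
#' @examples
#' \donttest{
#' cond <- dif_condition(quality = 0.2, rho = 0, pct_dif = 0.1,
#'                       dif_type = "uniform", size = 0.1,
#'                       sign_g = "+", sign_s = "+", N = 600)
#' dat <- sim_dif_data(cond, seed = 7)
#' scan <- dif_test(dat$x, dat$group, cond$q, methods = c("WXPD", "MH"))
#' summary(scan)
#' }
#' @export
dif_test <- function(x, group, q,
                     methods = c("Wd", "WXPD", "WObs", "WSw", "MH", "LR"),
                     alpha = 0.05, ...) {
  methods <- match.arg(methods,
                       c("Wd", "WXPD", "WObs", "WSw", "MH", "LR"),
                       several.ok = TRUE)
  x <- validate_binary_matrix(x, "x")
  group <- normalize_group(group, nrow(x))
  q <- validate_qmatrix(q)
  J <- nrow(q)
  if (ncol(x) != J) stop_with("dinadif_invalid", "ncol(x) must equal nrow(q)")

  wald_methods <- intersect(c("Wd", "WXPD", "WObs", "WSw"), methods)
  fits <- NULL
  deltas <- NULL
  rows <- list()

  if (length(wald_methods)) {
    fits <- dina_groups(x, group, q, ...)
    deltas <- data.frame(
      item = seq_len(J),
      delta_g = fits$focal$guess - fits$reference$guess,
      delta_s = fits$reference$slip - fits$focal$slip)
    caches <- lapply(fits, .wald_cov_cache, wald_methods = wald_methods)
    for (m in wald_methods) {
      for (j in seq_len(J)) {
        v <- c(fits$focal$guess[j], fits$focal$slip[j],
               fits$reference$guess[j], fits$reference$slip[j])
        st <- tryCatch(
          wald_stat(v, item_cov_block(caches$focal[[m]],
                                      caches$reference[[m]], j)),
          dinadif_singular = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          item = j, method = m,
          statistic = if (is.null(st)) NA_real_ else st$statistic,
          df = 2L,
          p_value = if (is.null(st)) NA_real_ else st$p_value)
      }
    }
  }
  if ("MH" %in% methods) {
    for (j in seq_len(J)) {
      st <- tryCatch(mh_test(score_strata(x, group, j)),
                     dinadif_untestable = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        item = j, method = "MH",
        statistic = if (is.null(st)) NA_real_ else st$statistic,
        df = 1L,
        p_value = if (is.null(st)) NA_real_ else st$p_value)
    }
  }
  if ("LR" %in% methods) {
    for (j in seq_len(J)) {
      st <- tryCatch(lr_test(x, group, j),
                     dinadif_untestable = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        item = j, method = "LR",
        statistic = if (is.null(st)) NA_real_ else st$statistic,
        df = 2L,
        p_value = if (is.null(st)) NA_real_ else st$p_value)
    }
  }

  res <- do.call(rbind, rows)
  res$method <- factor(res$method, levels = methods)
  res <- res[order(res$method, res$item), ]
  rownames(res) <- NULL
  res$flagged <- res$p_value < alpha

  structure(list(results = res, alpha = alpha, methods = methods,
                 fits = fits, deltas = deltas, call = match.call()),
            class = "dina_dif")
}
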