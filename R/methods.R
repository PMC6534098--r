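# S3 methods for the fitted-model and DIF-scan classes.

#' @export
print.dina <- function(x, ...) {
  cat("DINA model fit (marginal ML via EM)\n")
  cat(sprintf("  %d examinees, %d items, %d attributes (%d latent classes)\n",
              x$N, x$J, x$K, x$L))
  cat(sprintf("  log-likelihood: %.3f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  guess: %.3f .. %.3f   slip: %.3f .. %.3f\n",
              min(x$guess), max(x$guess), min(x$slip), max(x$slip)))
  invisible(x)
}

#' Summarise a DINA fit
#'
#' Item parameter table with asymptotic standard errors from the chosen
#' covariance estimator, plus the size of the largest latent classes.
#'
#' @param object A `"dina"` fit.
#' @param se_type Covariance estimator for the standard errors
#'   (`"xpd"`, cheap and default; `"obs"` or `"sandwich"` require a
#'   finite-difference Hessian; `"none"` skips them).
#' @param ... Unused.
#' @export
summary.dina <- function(object, se_type = c("xpd", "obs", "sandwich", "none"),
                         ...) {
  se_type <- match.arg(se_type)
  J <- object$J
  tab <- data.frame(item = seq_len(J), guess = unname(object$guess),
                    slip = unname(object$slip))
  if (se_type != "none" && !is.null(object$x)) {
    V <- vcov(object, type = se_type)
    se <- sqrt(pmax(diag(V), 0))
    tab$se_guess <- se[seq(1L, 2L * J, by = 2L)]
    tab$se_slip <- se[seq(2L, 2L * J, by = 2L)]
  }
  out <- list(items = tab,
              class_probs = object$class_probs,
              patterns = object$patterns,
              loglik = object$loglik, converged = object$converged,
              n_iter = object$n_iter, N = object$N, npar = object$npar,
              se_type = se_type)
  class(out) <- "summary.dina"
  out
}

#' @export
print.summary.dina <- function(x, digits = 3, ...) {
  cat(sprintf("DINA fit: N = %d, logLik = %.3f (%s, %d EM iterations)\n\n",
              x$N, x$loglik, if (x$converged) "converged" else "not converged",
              x$n_iter))
  print(round(x$items, digits))
  top <- order(x$class_probs, decreasing = TRUE)[seq_len(min(5, length(x$class_probs)))]
  cat("\nLargest latent classes:\n")
  for (l in top)
    cat(sprintf("  [%s]  p = %.3f\n",
                paste(x$patterns[l, ], collapse = ""), x$class_probs[l]))
  invisible(x)
}

#' @export
coef.dina <- function(object, ...) {
  setNames(pack_beta(object$guess, object$slip, object$eta),
           beta_labels(object$J, object$L))
}

#' @export
logLik.dina <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$N,
            class = "logLik")
}

#' Asymptotic covariance of a DINA fit
#'
#' @param object A `"dina"` fit estimated with `keep_data = TRUE`.
#' @param type `"xpd"` (inverse cross-product information), `"obs"`
#'   (inverse observed information), `"sandwich"`
#'   (\eqn{I_{Obs}^{-1} I_{XPD} I_{Obs}^{-1}}), or `"itemwise"` (list of
#'   per-item 2 x 2 blocks, the W_d approximation).
#' @param ... Unused.
#' @return A square matrix over the interior parameters (structural
#'   parameters of boundary classes are excluded, see [free_params()];
#'   the first 2J rows/columns are always the item parameters), or a
#'   list of 2 x 2 matrices for `type = "itemwise"`.
#' @export
vcov.dina <- function(object, type = c("xpd", "obs", "sandwich", "itemwise"),
                      ...) {
  type <- match.arg(type)
  if (is.null(object$x))
    stop_with("dinadif_invalid", "fit was run with keep_data = FALSE")
  if (type == "itemwise") return(itemwise_vcov(object))
  idx <- free_params(object)
  xpd <- NULL; obs <- NULL
  if (type %in% c("xpd", "sandwich"))
    xpd <- info_xpd(dina_scores(object$x, object$guess, object$slip,
                                object$eta, object$q))[idx, idx]
  if (type %in% c("obs", "sandwich"))
    obs <- info_obs(object$x, object$guess, object$slip, object$eta,
                    object$q)[idx, idx]
  info_to_vcov(type, xpd = xpd, obs = obs)
}

#' Posterior predictions from a DINA fit
#'
#' @param object A `"dina"` fit.
#' @param newdata Optional response matrix; defaults to the training
#'   data.
#' @param type `"posterior"` (N x L class membership probabilities),
#'   `"class"` (MAP attribute pattern per examinee, N x K), or
#'   `"response"` (posterior-expected correct-response probability per
#'   examinee and item).
#' @param ... Unused.
#' @export
predict.dina <- function(object, newdata = NULL,
                         type = c("posterior", "class", "response"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else validate_binary_matrix(newdata, "newdata")
  if (is.null(x)) stop_with("dinadif_invalid", "no data available for prediction")
  W <- dina_posterior(x, object$guess, object$slip, object$eta, object$q)
  switch(type,
    posterior = W,
    class = object$patterns[max.col(W, ties.method = "first"), , drop = FALSE],
    response = W %*% .resp_probs(object$guess, object$slip, object$gamma))
}

#' Simulate response data from a fitted DINA model
#'
#' Draws attribute patterns from the fitted class distribution and
#' responses from the fitted item parameters.
#'
#' @param object A `"dina"` fit.
#' @param nsim Number of data sets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` binary N x J matrices.
#' @export
simulate.dina <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    cls <- sample.int(object$L, object$N, replace = TRUE,
                      prob = object$class_probs)
    sim_dina_responses(object$patterns[cls, , drop = FALSE],
                       object$guess, object$slip, object$q)
  })
}

#' @export
residuals.dina <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  if (is.null(object$x))
    stop_with("dinadif_invalid", "fit was run with keep_data = FALSE")
  phat <- object$posterior %*% .resp_probs(object$guess, object$slip,
                                           object$gamma)
  r <- object$x - phat
  if (type == "pearson") r <- r / sqrt(phat * (1 - phat))
  r
}

#' @export
plot.dina <- function(x, ...) {
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b", pch = 20,
       xlab = "EM iteration", ylab = "marginal log-likelihood",
       main = "EM ascent", ...)
  invisible(x)
}

#' @export
print.dina_dif <- function(x, ...) {
  n_flag <- tapply(x$results$flagged, x$results$method,
                   function(z) sum(z, na.rm = TRUE))
  cat(sprintf("DIF scan of %d items at alpha = %g\n",
              max(x$results$item), x$alpha))
  for (m in x$methods)
    cat(sprintf("  %-5s flagged %d item(s)\n", m, n_flag[[m]]))
  invisible(x)
}

#' @export
summary.dina_dif <- function(object, ...) {
  res <- object$results
  flagged <- res[!is.na(res$flagged) & res$flagged, , drop = FALSE]
  cat(sprintf("DIF scan: %d items x %d methods, alpha = %g\n",
              max(res$item), length(object$methods), object$alpha))
  if (nrow(flagged) == 0L) {
    cat("No items flagged.\n")
  } else {
    cat("Flagged items:\n")
    print(flagged, row.names = FALSE, digits = 4)
  }
  if (anyNA(res$p_value))
    cat(sprintf("%d untestable (item, method) pairs reported as NA.\n",
                sum(is.na(res$p_value))))
  invisible(object)
}

#' @export
as.data.frame.dina_dif <- function(x, ...) x$results

#' @export
plot.dina_dif <- function(x, method = x$methods[1L], ...) {
  res <- x$results[x$results$method == method, , drop = FALSE]
  lp <- -log10(res$p_value)
  barplot(lp, names.arg = res$item, xlab = "item",
          ylab = expression(-log[10](p)),
          main = sprintf("DIF scan (%s)", method), ...)
  abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}

#' @export
print.dif_study <- function(x, digits = 3, ...) {
  cat(sprintf("Monte Carlo DIF study: %d condition(s), %d replications each\n\n",
              length(unique(x$condition)), attr(x, "n_reps")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
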