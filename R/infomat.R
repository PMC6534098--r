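# Information matrices and asymptotic covariances for the full parameter
# vector beta = (g_1, s_1, ..., g_J, s_J, eta_1, ..., eta_{L-1}).
#
# Scores are analytic.  Writing w_nl for the posterior class weight and
# p_l for the prior class probability,
#   d log L_n / d g_j  = (x_nj - g_j) / (g_j (1 - g_j)) * sum_{l: gamma=0} w_nl
#   d log L_n / d s_j  = -(x_nj - (1 - s_j)) / (s_j (1 - s_j)) * sum_{l: gamma=1} w_nl
#   d log L_n / d eta_l = w_nl - p_l                       (l = 1 .. L-1)
# The observed information is obtained by central finite differences of
# the analytic score (no closed-form Hessian is used).

#' Per-examinee score vectors
#'
#' Gradient of each examinee's log marginal likelihood with respect to
#' the full parameter vector, in the fixed order
#' \eqn{(g_1, s_1, \ldots, g_J, s_J, \eta_1, \ldots, \eta_{L-1})}.
#'
#' @inheritParams dina_loglik
#' @return An N x (2J + L - 1) matrix with labelled columns; column sums
#'   vanish at the MLE.
#' @export
dina_scores <- function(x, guess, slip, eta, q) {
  d <- .prep_xq(x, q)
  .check_item_params(guess, slip)
  X <- d$x; gam <- d$gam
  N <- nrow(X); J <- ncol(X); L <- nrow(gam)
  if (length(eta) != L - 1L)
    stop_with("dinadif_invalid", "`eta` must have length 2^K - 1")
  es <- .estep(X, 1 - X, gam, guess, slip, eta)
  W <- es$W
  p <- class_probs(eta)

  G0 <- W %*% (1 - gam)
  G1 <- W %*% gam
  Gm <- matrix(guess, N, J, byrow = TRUE)
  Sm <- matrix(slip, N, J, byrow = TRUE)
  Sg <- (X - Gm) / (Gm * (1 - Gm)) * G0
  Ss <- -(X - (1 - Sm)) / (Sm * (1 - Sm)) * G1
  Se <- sweep(W[, -L, drop = FALSE], 2L, p[-L], `-`)

  S <- matrix(0, N, 2L * J + L - 1L)
  S[, seq(1L, 2L * J, by = 2L)] <- Sg
  S[, seq(2L, 2L * J, by = 2L)] <- Ss
  S[, (2L * J + 1L):(2L * J + L - 1L)] <- Se
  colnames(S) <- beta_labels(J, L)
  S
}

#' Cross-product (XPD) information matrix
#'
#' Sum over examinees of the outer products of their score vectors,
#' \eqn{\sum_n s_n s_n'}; symmetric and positive semi-definite by
#' construction.
#'
#' @param scores N x P score matrix from [dina_scores()].
#' @return A symmetric P x P matrix.
#' @export
info_xpd <- function(scores) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores)))
    stop_with("dinadif_unstable", "non-finite score entries")
  I <- crossprod(scores)
  dimnames(I) <- list(colnames(scores), colnames(scores))
  I
}

#' Observed information matrix
#'
#' Negative Hessian of the total log-likelihood, computed by central
#' finite differences of the analytic score with per-parameter step
#' \eqn{h_p = h \max(1, |\beta_p|)}, then symmetrised as
#' \eqn{(H + H')/2}.
#'
#' @inheritParams dina_loglik
#' @param h Relative finite-difference step.
#' @return A symmetric P x P matrix.
#' @export
info_obs <- function(x, guess, slip, eta, q, h = 1e-5) {
  d <- .prep_xq(x, q)
  .check_item_params(guess, slip)
  J <- ncol(d$x)
  beta <- pack_beta(guess, slip, eta)
  P <- length(beta)
  gfun <- function(b) {
    pr <- unpack_beta(b, J)
    colSums(dina_scores(d$x, pr$guess, pr$slip, pr$eta, d$q))
  }
  H <- matrix(0, P, P)
  for (p in seq_len(P)) {
    hp <- h * max(1, abs(beta[p]))
    bp <- beta; bp[p] <- beta[p] + hp
    bm <- beta; bm[p] <- beta[p] - hp
    H[, p] <- (gfun(bp) - gfun(bm)) / (2 * hp)
  }
  I <- -(H + t(H)) / 2
  if (any(!is.finite(I)))
    stop_with("dinadif_unstable", "non-finite entries in the observed information")
  dimnames(I) <- list(beta_labels(J, length(eta) + 1L),
                      beta_labels(J, length(eta) + 1L))
  I
}

.safe_inverse <- function(M, rcond_tol = 1e-12, what = "information matrix") {
  rc <- rcond(M)
  if (!is.finite(rc) || rc < rcond_tol)
    stop_with("dinadif_singular",
              sprintf("%s is numerically singular (rcond = %.3g)", what, rc))
  V <- solve(M)
  (V + t(V)) / 2
}

#' Covariance matrix from information matrices
#'
#' XPD and Obs covariances are plain inverses; the sandwich covariance
#' is \eqn{I_{Obs}^{-1} I_{XPD} I_{Obs}^{-1}}.  When the XPD and Obs
#' matrices coincide (as they do asymptotically under correct model
#' specification) all three kinds return the same inverse.
#'
#' @param kind One of `"xpd"`, `"obs"`, `"sandwich"`.
#' @param xpd,obs The information matrices the chosen kind requires.
#' @param rcond_tol Reciprocal condition number below which the
#'   inversion aborts with a singular-information error.
#' @return A symmetric covariance matrix for the full parameter vector.
#' @export
info_to_vcov <- function(kind = c("xpd", "obs", "sandwich"),
                         xpd = NULL, obs = NULL, rcond_tol = 1e-12) {
  kind <- match.arg(kind)
  need <- function(M, nm) {
    if (is.null(M))
      stop_with("dinadif_invalid", sprintf("`%s` information required for kind '%s'", nm, kind))
    as.matrix(M)
  }
  switch(kind,
    xpd = .safe_inverse(need(xpd, "xpd"), rcond_tol, "XPD information"),
    obs = .safe_inverse(need(obs, "obs"), rcond_tol, "observed information"),
    sandwich = {
      Vo <- .safe_inverse(need(obs, "obs"), rcond_tol, "observed information")
      V <- Vo %*% need(xpd, "xpd") %*% Vo
      (V + t(V)) / 2
    })
}

#' Indices of the interior (free) parameters of a fit
#'
#' The EM solution can place latent classes on the boundary of the
#' structural space (estimated class probability numerically zero).
#' Boundary parameters have no interior MLE and contribute numerically
#' null rows to the information matrix, so covariance estimation drops
#' them before inversion.  Item parameters are always retained (they are
#' clipped into the interior during estimation).
#'
#' @param object A `"dina"` fit.
#' @param tol Class-probability threshold below which a structural
#'   parameter counts as being on the boundary.
#' @return Integer vector of positions into the packed parameter vector.
#' @export
free_params <- function(object, tol = 1e-6) {
  stopifnot(inherits(object, "dina"))
  idx <- seq_len(object$npar)
  drop_eta <- which(object$class_probs[-object$L] < tol)
  if (length(drop_eta)) idx <- idx[-(2L * object$J + drop_eta)]
  idx
}

#' Item-wise covariance blocks
#'
#' The per-item approximation underlying the classical Wald DIF test
#' W_d: for each item j invert the 2 x 2 cross-product of per-examinee
#' score contributions with respect to \eqn{(g_j, s_j)} only, holding
#' the posterior class weights fixed at the fit and ignoring structural
#' parameters and every cross-item block.  Ignoring those blocks is what
#' makes this estimator underestimate the sampling variance.
#'
#' @param object A converged `"dina"` fit (with stored data).
#' @param rcond_tol Singularity guard for the 2 x 2 inversions.
#' @return A list of J symmetric 2 x 2 matrices (rows/cols `g`, `s`).
#' @export
itemwise_vcov <- function(object, rcond_tol = 1e-12) {
  stopifnot(inherits(object, "dina"))
  if (is.null(object$x))
    stop_with("dinadif_invalid", "fit was run with keep_data = FALSE")
  if (!object$converged)
    warning("fit did not converge; item-wise covariance may be unreliable", call. = FALSE)
  S <- dina_scores(object$x, object$guess, object$slip, object$eta, object$q)
  lapply(seq_len(object$J), function(j) {
    B <- crossprod(S[, c(2L * j - 1L, 2L * j), drop = FALSE])
    V <- .safe_inverse(B, rcond_tol, sprintf("item-wise information for item %d", j))
    dimnames(V) <- list(c("g", "s"), c("g", "s"))
    V
  })
}

#' Two-group covariance block for one item
#'
#' Assembles the 4 x 4 covariance \eqn{\Sigma_j} of
#' \eqn{v_j' = (g_{Fj}, s_{Fj}, g_{Rj}, s_{Rj})} as the block-diagonal
#' of the focal and reference \eqn{(g_j, s_j)} blocks.  The
#' focal-reference off-diagonal blocks are exactly zero because the two
#' groups are independent samples.
#'
#' @param cov_focal,cov_reference Either full covariance matrices over
#'   beta (from [info_to_vcov()]) or item-wise block lists (from
#'   [itemwise_vcov()]); both must come from the same estimator kind.
#' @param j Item index.
#' @return A symmetric 4 x 4 matrix with rows/cols `gF, sF, gR, sR`.
#' @export
item_cov_block <- function(cov_focal, cov_reference, j) {
  pick <- function(cv) {
    if (is.list(cv)) {
      if (j < 1L || j > length(cv))
        stop_with("dinadif_invalid", "item index out of range")
      cv[[j]]
    } else {
      idx <- c(2L * j - 1L, 2L * j)
      if (j < 1L || max(idx) > nrow(cv))
        stop_with("dinadif_invalid", "item index out of range")
      cv[idx, idx, drop = FALSE]
    }
  }
  S <- matrix(0, 4L, 4L)
  S[1:2, 1:2] <- pick(cov_focal)
  S[3:4, 3:4] <- pick(cov_reference)
  dimnames(S) <- list(c("gF", "sF", "gR", "sR"), c("gF", "sF", "gR", "sR"))
  S
}
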