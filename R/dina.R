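# DINA marginal likelihood and EM estimation.
#
# Model: P(x_nj = 1 | alpha_l) = g_j^(1 - gamma_lj) (1 - s_j)^gamma_lj,
# with class probabilities softmax(eta, 0).  The marginal likelihood sums
# the class-conditional Bernoulli products over all L = 2^K classes; all
# computations run in log space with a per-examinee log-sum-exp so J = 30
# response patterns never underflow.

.resp_probs <- function(guess, slip, gam) {
  L <- nrow(gam); J <- ncol(gam)
  gam * matrix(1 - slip, L, J, byrow = TRUE) +
    (1 - gam) * matrix(guess, L, J, byrow = TRUE)
}

# E-step quantities at the supplied parameters: posterior class weights,
# per-examinee log marginal likelihoods, and their sum.
.estep <- function(X, Xc, gam, guess, slip, eta) {
  P <- .resp_probs(guess, slip, gam)
  ll <- X %*% t(log(P)) + Xc %*% t(log1p(-P))       # N x L
  lw <- sweep(ll, 2L, log(class_probs(eta)), `+`)
  m <- lw[cbind(seq_len(nrow(lw)), max.col(lw, ties.method = "first"))]
  logLn <- m + log(rowSums(exp(lw - m)))
  list(W = exp(lw - logLn), logLn = logLn, loglik = sum(logLn))
}

.check_item_params <- function(guess, slip) {
  if (any(!is.finite(guess)) || any(!is.finite(slip)) ||
      any(guess <= 0 | guess >= 1) || any(slip <= 0 | slip >= 1))
    stop_with("dinadif_invalid",
              "guess and slip parameters must lie strictly inside (0, 1)")
}

#' Class-conditional response probabilities
#'
#' The L x J table \eqn{P_{lj} = g_j^{1-\gamma_{lj}} (1-s_j)^{\gamma_{lj}}}:
#' masters of all required attributes answer with probability \eqn{1 - s_j},
#' everyone else guesses with probability \eqn{g_j}.
#'
#' @param guess,slip Per-item guessing and slipping probabilities in (0, 1).
#' @param q Q-matrix (J x K).
#' @param patterns Optional class-by-attribute matrix; defaults to the full
#'   enumeration for `ncol(q)` attributes.
#' @return An L x J matrix of probabilities in (0, 1).
#' @export
dina_response_probs <- function(guess, slip, q, patterns = NULL) {
  q <- validate_qmatrix(q)
  .check_item_params(guess, slip)
  if (length(guess) != nrow(q) || length(slip) != nrow(q))
    stop_with("dinadif_invalid", "one guess and one slip value per item required")
  if (is.null(patterns)) patterns <- attr_patterns(ncol(q))
  .resp_probs(guess, slip, gamma_matrix(patterns, q))
}

.prep_xq <- function(x, q) {
  x <- validate_binary_matrix(x, "x")
  q <- validate_qmatrix(q)
  if (ncol(x) != nrow(q))
    stop_with("dinadif_invalid", "ncol(x) must equal nrow(q)")
  list(x = x, q = q, gam = gamma_matrix(attr_patterns(ncol(q)), q))
}

#' Marginal log-likelihood of a DINA parameter set
#'
#' @param x N x J binary response matrix.
#' @param guess,slip Item parameters in (0, 1).
#' @param eta Structural vector of length \eqn{2^K - 1} (last class fixed
#'   at zero).
#' @param q Q-matrix.
#' @return The scalar marginal log-likelihood.
#' @export
dina_loglik <- function(x, guess, slip, eta, q) {
  d <- .prep_xq(x, q)
  .check_item_params(guess, slip)
  if (length(eta) != nrow(d$gam) - 1L)
    stop_with("dinadif_invalid", "`eta` must have length 2^K - 1")
  .estep(d$x, 1 - d$x, d$gam, guess, slip, eta)$loglik
}

#' Posterior attribute-class probabilities
#'
#' Row n is proportional to \eqn{p(\alpha_l \mid \eta) \prod_j
#' P_{lj}^{x_{nj}} (1 - P_{lj})^{1 - x_{nj}}}; rows sum to one.
#'
#' @inheritParams dina_loglik
#' @return An N x L matrix of posterior membership probabilities.
#' @export
dina_posterior <- function(x, guess, slip, eta, q) {
  d <- .prep_xq(x, q)
  .check_item_params(guess, slip)
  .estep(d$x, 1 - d$x, d$gam, guess, slip, eta)$W
}

#' Fit the DINA model by marginal maximum likelihood
#'
#' EM estimation over the \eqn{2^K} latent classes.  The E-step computes
#' posterior class weights; the M-step updates guess/slip from expected
#' counts of non-masters/masters and the structural vector from mean
#' posterior weights.  Updated item parameters are clipped to
#' `[eps, 1 - eps]` so every subsequent information matrix stays finite.
#' No monotonicity constraint (such as \eqn{g_j < 1 - s_j}) is imposed.
#'
#' @param x N x J binary response matrix (no missing values).
#' @param q J x K binary Q-matrix.
#' @param tol Convergence tolerance: the fit stops once the maximum
#'   absolute change over guess, slip and the class probabilities falls
#'   below `tol`.  The structural change is measured on the probability
#'   scale rather than on eta because a latent class heading to the
#'   boundary (probability zero) sends its eta to minus infinity along a
#'   likelihood-flat direction; on the eta scale such fits would never
#'   register as converged although every estimate of interest is
#'   stationary.
#' @param max_iter Maximum EM iterations; exceeding it yields
#'   `converged = FALSE`, never an error.
#' @param init Named list with starting values `guess`, `slip` (scalars
#'   or per-item vectors) and optionally `eta` (defaults to uniform
#'   classes).
#' @param eps Clipping bound keeping item parameters interior.
#' @param keep_data Store the response matrix in the fit (needed by
#'   [vcov.dina()] and [residuals.dina()]).
#' @return An object of class `"dina"`: a list with elements `guess`,
#'   `slip`, `eta`, `class_probs`, `posterior`, `loglik`,
#'   `loglik_trace`, `converged`, `n_iter`, `patterns`, `gamma`, `q`,
#'   `npar`, and (if `keep_data`) `x`.
#' @examples
#' q <- attr_patterns(2)[-1, , drop = FALSE]  # 3 items, 2 attributes
#' set.seed(1)
#' alpha <- sim_attributes(300, K = 2, rho = 0)
#' x <- sim_dina_responses(alpha, guess = rep(0.2, 3), slip = rep(0.2, 3), q = q)
#' fit <- dina(x, q)
#' coef(fit)[1:6]
#' @export
dina <- function(x, q, tol = 1e-4, max_iter = 1000L,
                 init = list(guess = 0.2, slip = 0.2),
                 eps = 1e-4, keep_data = TRUE) {
  d <- .prep_xq(x, q)
  X <- d$x; Xc <- 1 - X; gam <- d$gam
  N <- nrow(X); J <- ncol(X); K <- ncol(d$q); L <- nrow(gam)
  if (N < 1L) stop_with("dinadif_invalid", "at least one examinee required")

  guess <- rep_len(if (is.null(init$guess)) 0.2 else init$guess, J)
  slip  <- rep_len(if (is.null(init$slip))  0.2 else init$slip,  J)
  eta   <- if (is.null(init$eta)) rep(0, L - 1L) else rep_len(init$eta, L - 1L)
  .check_item_params(guess, slip)

  trace <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    es <- .estep(X, Xc, gam, guess, slip, eta)
    trace[it] <- es$loglik
    W <- es$W

    R0 <- W %*% (1 - gam)                    # expected non-master exposure
    R1 <- W %*% gam                          # expected master exposure
    g_new <- clip01(colSums(X * R0) / colSums(R0), eps)
    s_new <- clip01(1 - colSums(X * R1) / colSums(R1), eps)
    p_new <- pmax(colMeans(W), 1e-12)
    p_new <- p_new / sum(p_new)
    eta_new <- log(p_new[-L] / p_new[L])

    delta <- max(abs(c(g_new - guess, s_new - slip,
                       p_new - class_probs(eta))))
    guess <- g_new; slip <- s_new; eta <- eta_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  final <- .estep(X, Xc, gam, guess, slip, eta)

  structure(list(
    guess = setNames(guess, paste0("g", seq_len(J))),
    slip = setNames(slip, paste0("s", seq_len(J))),
    eta = setNames(eta, paste0("eta", seq_len(L - 1L))),
    class_probs = class_probs(eta),
    posterior = final$W,
    loglik = final$loglik,
    loglik_trace = c(trace[seq_len(it)], final$loglik),
    converged = converged,
    n_iter = it,
    patterns = attr_patterns(K),
    gamma = gam,
    q = d$q,
    N = N, J = J, K = K, L = L,
    npar = 2L * J + L - 1L,
    x = if (keep_data) X else NULL,
    call = match.call()
  ), class = "dina")
}

#' Fit the DINA model separately in two groups
#'
#' Independent EM fits for the reference and the focal group, each with
#' its own item and structural parameters.  With every parameter
#' group-specific the two-group likelihood factorises, so the joint MLE
#' is exactly the pair of single-group MLEs and the joint covariance is
#' block-diagonal across groups.
#'
#' @param x N x J binary response matrix (both groups stacked).
#' @param group Group labels; anything [normalizable][dif_test] to
#'   reference/focal ("R"/"F", 0/1, "reference"/"focal").
#' @param q Q-matrix.
#' @param ... Passed on to [dina()].
#' @return A list with components `reference` and `focal`, each a
#'   `"dina"` fit.
#' @export
dina_groups <- function(x, group, q, ...) {
  x <- validate_binary_matrix(x, "x")
  group <- normalize_group(group, nrow(x))
  q <- validate_qmatrix(q)
  J <- nrow(q)
  out <- lapply(c(reference = "reference", focal = "focal"), function(gl) {
    idx <- group == gl
    if (sum(idx) < 2L * J)
      warning(sprintf("%s group has only %d examinees (< 2J = %d); estimates may be unstable",
                      gl, sum(idx), 2L * J), call. = FALSE)
    dina(x[idx, , drop = FALSE], q, ...)
  })
  out
}
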