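# Synthetic-data generator: the 30 x 5 study Q-matrix, correlated binary
# attribute profiles, DINA response simulation, DIF injection, and the
# full factorial condition grid.

#' The 30 x 5 simulation Q-matrix
#'
#' The balanced Q-matrix used throughout the simulation design: each of
#' the five attributes is measured by exactly 12 items, and the item
#' complexity (row sums) follows the pattern 1,1,1,1,1,2,2,2,2,2,
#' 3,3,3,3,3 repeated twice.  Also shipped as a plain-text fixture in
#' `inst/extdata/qmatrix_sim.csv`.
#'
#' @return A 30 x 5 binary matrix.
#' @export
sim_qmatrix <- function() {
  q <- matrix(c(
    1,0,0,0,0,
    0,1,0,0,0,
    0,0,1,0,0,
    0,0,0,1,0,
    0,0,0,0,1,
    1,1,0,0,0,
    1,0,0,0,1,
    0,1,1,0,0,
    0,0,1,1,0,
    0,0,0,1,1,
    1,1,1,0,0,
    1,1,0,0,1,
    1,0,0,1,1,
    0,1,1,1,0,
    0,0,1,1,1,
    1,0,0,0,0,
    0,1,0,0,0,
    0,0,1,0,0,
    0,0,0,1,0,
    0,0,0,0,1,
    1,0,1,0,0,
    1,0,0,1,0,
    0,1,0,1,0,
    0,1,0,0,1,
    0,0,1,0,1,
    1,1,0,1,0,
    1,0,1,1,0,
    1,0,1,0,1,
    0,1,1,0,1,
    0,1,0,1,1), nrow = 30, ncol = 5, byrow = TRUE)
  colnames(q) <- paste0("A", 1:5)
  q
}

#' Simulate correlated binary attribute profiles
#'
#' Draws K-variate standard normal vectors with an exchangeable
#' correlation `rho` (one common factor: \eqn{z_k = \sqrt{\rho}\, z_0 +
#' \sqrt{1-\rho}\, e_k}) and thresholds them at zero, so each attribute
#' is mastered with marginal probability 0.5 and every attribute pair
#' shares tetrachoric correlation `rho`.
#'
#' @param n Number of examinees.
#' @param K Number of attributes.
#' @param rho Exchangeable attribute correlation in `[0, 1)`.
#' @return An n x K binary matrix.
#' @export
sim_attributes <- function(n, K = 5, rho = 0) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho >= 1)
    stop_with("dinadif_invalid", "`rho` must lie in [0, 1)")
  z0 <- rnorm(n)
  z <- sqrt(rho) * z0 + sqrt(1 - rho) * matrix(rnorm(n * K), n, K)
  a <- matrix(as.integer(z > 0), n, K)
  colnames(a) <- paste0("A", seq_len(K))
  a
}

.parse_sign <- function(s, what) {
  if (is.numeric(s)) {
    if (!s %in% c(-1, 0, 1))
      stop_with("dinadif_invalid", sprintf("`%s` must be +1, 0 or -1", what))
    return(as.integer(s))
  }
  out <- c("+" = 1L, "0" = 0L, "-" = -1L)[as.character(s)]
  if (is.na(out)) stop_with("dinadif_invalid", sprintf("`%s` must be '+', '0' or '-'", what))
  unname(out)
}

#' Inject DIF into reference item parameters
#'
#' Builds focal-group parameters from the reference values via
#' \eqn{\Delta_g = g_F - g_R} and \eqn{\Delta_s = s_R - s_F}: on DIF
#' items \eqn{g_F = g_R + sign_g \cdot size} and \eqn{s_F = s_R -
#' sign_s \cdot size} (a "+" slip pattern *lowers* the focal slip,
#' advantaging the focal group).  Non-DIF items are untouched.
#'
#' @param guess,slip Reference-group item parameter vectors.
#' @param dif_items Indices of the items carrying DIF.
#' @param size DIF effect size (0.05 or 0.1 in the study design).
#' @param sign_g,sign_s Signs of the two deltas: `"+"`, `"0"`, `"-"` (or
#'   +1/0/-1).
#' @return List with focal `guess` and `slip` vectors.
#' @export
apply_dif <- function(guess, slip, dif_items, size, sign_g, sign_s) {
  sg <- .parse_sign(sign_g, "sign_g")
  ss <- .parse_sign(sign_s, "sign_s")
  if (length(dif_items) && (min(dif_items) < 1L || max(dif_items) > length(guess)))
    stop_with("dinadif_invalid", "`dif_items` out of range")
  g <- guess; s <- slip
  g[dif_items] <- guess[dif_items] + sg * size
  s[dif_items] <- slip[dif_items] - ss * size
  if (any(g <= 0 | g >= 1) || any(s <= 0 | s >= 1))
    stop_with("dinadif_invalid",
              "injected DIF pushes a focal parameter outside (0, 1)")
  list(guess = g, slip = s)
}

#' Simulate DINA responses
#'
#' Draws \eqn{x_{nj} \sim Bernoulli(P_{nj})} with \eqn{P_{nj} =
#' g_j^{1-\gamma_{nj}} (1 - s_j)^{\gamma_{nj}}} from each examinee's
#' attribute profile.
#'
#' @param alpha N x K binary attribute matrix.
#' @param guess,slip Item parameters in (0, 1).
#' @param q Q-matrix.
#' @return An N x J binary response matrix.
#' @export
sim_dina_responses <- function(alpha, guess, slip, q) {
  alpha <- validate_binary_matrix(alpha, "alpha")
  q <- validate_qmatrix(q)
  .check_item_params(guess, slip)
  gam <- gamma_matrix(alpha, q)          # here rows are examinees
  N <- nrow(alpha); J <- nrow(q)
  P <- gam * matrix(1 - slip, N, J, byrow = TRUE) +
    (1 - gam) * matrix(guess, N, J, byrow = TRUE)
  matrix(rbinom(N * J, 1L, P), N, J)
}

.default_dif_items <- function(pct_dif) {
  if (isTRUE(all.equal(pct_dif, 0.1))) c(1L, 11L, 21L)
  else if (isTRUE(all.equal(pct_dif, 0.3))) c(1L, 4L, 8L, 11L, 14L, 18L, 21L, 24L, 28L)
  else stop_with("dinadif_invalid", "no default DIF placement for this pct_dif; supply `dif_items`")
}

#' Define one simulation condition
#'
#' A condition bundles everything one Monte Carlo cell needs: the
#' reference item quality (common `s = g` value), the attribute
#' correlation, the share and placement of DIF items, and the DIF sign
#' pattern and size.  The focal parameters are derived immediately via
#' [apply_dif()], which also enforces that low item quality (0.1) is
#' incompatible with the large DIF size (0.1) — the focal parameters
#' would hit the boundary of (0, 1).
#'
#' @param quality Reference slip and guessing value (0.1, 0.2 or 0.3 in
#'   the study design).
#' @param rho Exchangeable attribute correlation.
#' @param pct_dif Proportion of DIF items (0.1 or 0.3 for the default
#'   placement).
#' @param dif_type `"uniform"` or `"nonuniform"`; checked against the
#'   sign pattern.
#' @param size DIF effect size.
#' @param sign_g,sign_s Delta signs (`"+"`, `"0"`, `"-"`).
#' @param N Total examinees (split `n_ref` / `N - n_ref`).
#' @param n_ref Reference-group size; defaults to an equal split.
#' @param q Q-matrix; defaults to [sim_qmatrix()].
#' @param dif_items DIF item indices; defaults to a fixed placement
#'   spreading DIF over 1-, 2- and 3-attribute items
#'   ({1, 11, 21} at 10%, {1, 4, 8, 11, 14, 18, 21, 24, 28} at 30%).
#' @param alpha Significance level used when the condition is run.
#' @return Object of class `"dif_condition"`.
#' @export
dif_condition <- function(quality, rho, pct_dif, dif_type, size,
                          sign_g, sign_s, N = 1000L, n_ref = NULL,
                          q = sim_qmatrix(), dif_items = NULL,
                          alpha = 0.05) {
  q <- validate_qmatrix(q)
  J <- nrow(q); K <- ncol(q)
  if (quality <= 0 || quality >= 1)
    stop_with("dinadif_invalid", "`quality` must be in (0, 1)")
  if (isTRUE(all.equal(quality, 0.1)) && size > 0.05 + 1e-12)
    stop_with("dinadif_invalid",
              "low item quality (0.1) admits only the small DIF size (0.05)")
  dif_type <- match.arg(dif_type, c("uniform", "nonuniform"))
  sg <- .parse_sign(sign_g, "sign_g"); ss <- .parse_sign(sign_s, "sign_s")
  implied <- classify_dif_type(sg, ss)
  if (implied != dif_type)
    stop_with("dinadif_invalid",
              sprintf("sign pattern (%d, %d) implies %s DIF, not %s",
                      sg, ss, implied, dif_type))
  if (is.null(dif_items)) dif_items <- .default_dif_items(pct_dif)
  if (is.null(n_ref)) n_ref <- as.integer(round(N / 2))
  ref <- list(guess = rep(quality, J), slip = rep(quality, J))
  foc <- apply_dif(ref$guess, ref$slip, dif_items, size, sg, ss)
  structure(list(quality = quality, rho = rho, pct_dif = pct_dif,
                 dif_type = dif_type, size = size,
                 sign_g = sg, sign_s = ss,
                 dif_items = as.integer(dif_items),
                 N = as.integer(N), n_ref = as.integer(n_ref),
                 J = J, K = K, q = q,
                 ref = ref, focal = foc, alpha = alpha),
            class = "dif_condition")
}

#' Simulate one grouped data set under a condition
#'
#' Both groups share one attribute-generation process (no impact: the
#' groups differ only through the injected item parameters).  The
#' attribute draw and the response draw consume independent child
#' streams of `seed`, so the same profiles are obtained regardless of
#' how many responses are drawn afterwards.
#'
#' @param cond A [dif_condition()].
#' @param seed Integer seed; the same (condition, seed) pair always
#'   reproduces the identical data set.
#' @return List with the stacked response matrix `x`, the `group`
#'   factor (reference first), the true attribute matrix `alpha`, and
#'   the condition.
#' @export
sim_dif_data <- function(cond, seed) {
  stopifnot(inherits(cond, "dif_condition"))
  set.seed(child_seed(seed, 1L))
  alpha <- sim_attributes(cond$N, cond$K, cond$rho)
  group <- factor(rep(c("reference", "focal"),
                      times = c(cond$n_ref, cond$N - cond$n_ref)),
                  levels = c("reference", "focal"))
  set.seed(child_seed(seed, 2L))
  x <- matrix(0L, cond$N, cond$J)
  ridx <- group == "reference"
  x[ridx, ] <- sim_dina_responses(alpha[ridx, , drop = FALSE],
                                  cond$ref$guess, cond$ref$slip, cond$q)
  x[!ridx, ] <- sim_dina_responses(alpha[!ridx, , drop = FALSE],
                                   cond$focal$guess, cond$focal$slip, cond$q)
  list(x = x, group = group, alpha = alpha, condition = cond)
}

.sign_patterns <- function(dif_type) {
  if (dif_type == "uniform")
    data.frame(sign_g = c(1L, -1L), sign_s = c(1L, -1L))
  else
    data.frame(sign_g = c(1L, -1L, 1L, 0L, -1L, 0L),
               sign_s = c(-1L, 1L, 0L, 1L, 0L, -1L))
}

#' Full factorial grid of simulation conditions
#'
#' Crosses item quality (0.1, 0.2, 0.3), attribute correlation (0, 0.5,
#' 0.8), percentage of DIF items (10%, 30%), DIF size (0.05, 0.1) and
#' the Table of sign patterns (2 uniform + 6 non-uniform per size),
#' with the restriction that quality 0.1 admits only size 0.05.  This
#' yields 240 conditions: per (rho, pct) cell, 16 + 16 + 8 across the
#' three quality levels.
#'
#' @return Data frame with one row per condition and columns `quality`,
#'   `rho`, `pct_dif`, `dif_type`, `size`, `sign_g`, `sign_s`.  Feed a
#'   row to [dif_condition()] (or the whole frame to [run_study()]).
#' @export
dif_condition_grid <- function() {
  cells <- expand.grid(quality = c(0.1, 0.2, 0.3),
                       rho = c(0, 0.5, 0.8),
                       pct_dif = c(0.1, 0.3),
                       dif_type = c("uniform", "nonuniform"),
                       size = c(0.05, 0.1),
                       stringsAsFactors = FALSE)
  cells <- cells[!(cells$quality == 0.1 & cells$size == 0.1), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    pat <- .sign_patterns(cells$dif_type[i])
    cbind(cells[rep(i, nrow(pat)), , drop = FALSE], pat)
  }))
  out <- out[order(out$quality, out$rho, out$pct_dif, out$dif_type,
                   out$size, out$sign_g, out$sign_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
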