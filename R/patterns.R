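#' Enumerate all attribute mastery patterns
#'
#' Generates the \eqn{L = 2^K} binary mastery patterns (latent classes)
#' for \eqn{K} attributes.  The order is lexicographic with attribute 1
#' as the most significant bit: row \eqn{l} is the \eqn{K}-digit binary
#' expansion of \eqn{l - 1}.  The last row is therefore the full-mastery
#' pattern, which is the reference class whose structural parameter is
#' fixed at zero for identification.
#'
#' @param K Number of attributes, an integer between 1 and 12 (the hard
#'   cap guards against accidentally materialising a huge class space).
#' @return An integer matrix with \eqn{2^K} rows and \eqn{K} columns,
#'   columns named `A1 ... AK`.
#' @examples
#' attr_patterns(2)
#' @export
attr_patterns <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K != round(K) ||
      K < 1 || K > 12)
    stop_with("dinadif_invalid", "`K` must be a single integer in 1..12")
  K <- as.integer(K)
  L <- 2L^K
  pat <- matrix(0L, L, K)
  for (k in seq_len(K))
    pat[, k] <- as.integer(bitwAnd(0:(L - 1L), bitwShiftL(1L, K - k)) > 0L)
  colnames(pat) <- paste0("A", seq_len(K))
  pat
}

#' Latent class probabilities from structural parameters
#'
#' Maps the log-linear structural vector \eqn{\eta = (\eta_1, \ldots,
#' \eta_{L-1})} to class probabilities \eqn{p_l = \exp(\eta_l) / \sum_m
#' \exp(\eta_m)} with \eqn{\eta_L \equiv 0} for identification.
#'
#' @param eta Numeric vector of length \eqn{L - 1}; finite.
#' @return Probability vector of length \eqn{L}, strictly positive,
#'   summing to one.
#' @export
class_probs <- function(eta) {
  if (!is.numeric(eta) || length(eta) < 1L || any(!is.finite(eta)))
    stop_with("dinadif_invalid", "`eta` must be a finite numeric vector")
  z <- c(eta, 0)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Check a Q-matrix
#'
#' A Q-matrix is a J x K binary item-by-attribute loading matrix; every
#' item must require at least one attribute.
#'
#' @param q Matrix-like object.
#' @return The validated Q-matrix as a numeric matrix.
#' @export
validate_qmatrix <- function(q) {
  q <- validate_binary_matrix(q, "q")
  if (any(rowSums(q) == 0))
    stop_with("dinadif_invalid",
              sprintf("Q-matrix row %d has no required attribute",
                      which(rowSums(q) == 0)[1L]))
  q
}

#' Mastery indicator matrix
#'
#' Computes the DINA latent response \eqn{\gamma_{lj} = \prod_k
#' \alpha_{lk}^{q_{jk}}}: entry \eqn{(l, j)} is 1 exactly when class
#' \eqn{l} masters every attribute item \eqn{j} requires (non-required
#' attributes never penalise, i.e. \eqn{0^0 = 1}).
#'
#' @param patterns Class-by-attribute binary matrix, e.g. from
#'   [attr_patterns()].
#' @param q Q-matrix with the same number of attribute columns.
#' @return An L x J integer matrix.
#' @export
gamma_matrix <- function(patterns, q) {
  patterns <- validate_binary_matrix(patterns, "patterns")
  q <- validate_qmatrix(q)
  if (ncol(patterns) != ncol(q))
    stop_with("dinadif_invalid",
              "`patterns` and `q` disagree on the number of attributes")
  hit <- patterns %*% t(q)
  need <- rowSums(q)
  g <- matrix(as.integer(sweep(hit, 2L, need, `>=`)),
              nrow(patterns), nrow(q))
  dimnames(g) <- list(NULL, rownames(q))
  g
}
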