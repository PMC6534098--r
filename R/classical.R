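# Non-CDM DIF tests: Mantel-Haenszel and logistic regression, both
# matched on the observed total score (which includes the studied item;
# thin matching, the standard MH convention).

#' Stratify responses to one item by total score
#'
#' Builds the 2 x 2 contingency tables (group x correct) at every total
#' score level m = 1, ..., J - 1.  The extreme scores 0 and J are
#' excluded (the MH summation runs over m = 1..J-1, and those strata
#' carry no association information anyway), and any stratum with a zero
#' row or column margin is dropped.
#'
#' @param x N x J binary response matrix.
#' @param group Reference/focal labels.
#' @param item Index of the studied item.
#' @return Data frame with columns `m`, `A`, `B` (reference
#'   correct/incorrect), `C`, `D` (focal correct/incorrect); one row per
#'   retained stratum.
#' @export
score_strata <- function(x, group, item) {
  x <- validate_binary_matrix(x, "x")
  J <- ncol(x)
  if (item < 1L || item > J) stop_with("dinadif_invalid", "item index out of range")
  group <- normalize_group(group, nrow(x), require_both = FALSE)
  total <- rowSums(x)
  keep <- total >= 1 & total <= J - 1
  tab <- table(m = factor(total[keep], levels = seq_len(J - 1L)),
               grp = group[keep],
               resp = factor(x[keep, item], levels = c(1, 0)))
  out <- data.frame(m = seq_len(J - 1L),
                    A = as.vector(tab[, "reference", "1"]),
                    B = as.vector(tab[, "reference", "0"]),
                    C = as.vector(tab[, "focal", "1"]),
                    D = as.vector(tab[, "focal", "0"]))
  ok <- (out$A + out$B) > 0 & (out$C + out$D) > 0 &
        (out$A + out$C) > 0 & (out$B + out$D) > 0
  out[ok, , drop = FALSE]
}

#' Mantel-Haenszel DIF statistic
#'
#' \deqn{MH = \frac{\{|\sum_m [A_m - E(A_m)]| - 0.5\}^2}{\sum_m Var(A_m)}}
#' with \eqn{E(A_m) = N_{mR} N_{m1} / N_m} and
#' \eqn{Var(A_m) = N_{mR} N_{mF} N_{m1} N_{m0} / [N_m^2 (N_m - 1)]},
#' referred to chi-square with 1 df.  The continuity-corrected numerator
#' is applied exactly as written (no flooring at zero), so a table with
#' zero total association still yields \eqn{0.25 / \sum Var}.
#'
#' @param strata Output of [score_strata()].
#' @return List with `statistic`, `df` (= 1) and `p_value`.
#' @export
mh_test <- function(strata) {
  if (is.null(strata) || nrow(strata) == 0L)
    stop_with("dinadif_untestable", "no usable score strata")
  A <- strata$A; B <- strata$B; C <- strata$C; D <- strata$D
  Nm <- A + B + C + D
  NmR <- A + B; NmF <- C + D; N1 <- A + C; N0 <- B + D
  E <- NmR * N1 / Nm
  V <- NmR * NmF * N1 * N0 / (Nm^2 * (Nm - 1))
  sumV <- sum(V)
  if (!is.finite(sumV) || sumV <= 0)
    stop_with("dinadif_untestable", "zero Mantel-Haenszel variance")
  stat <- (abs(sum(A - E)) - 0.5)^2 / sumV
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Logistic-regression DIF test
#'
#' Fits the full model \eqn{logit(\pi_n) = \tau_0 + \tau_1 M_n + \tau_2
#' G_n + \tau_3 M_n G_n} (M = total score, G = group with reference
#' coded 0 and focal 1) and the matching-only reduction \eqn{\tau_0 +
#' \tau_1 M_n}, and reports the 2-df likelihood-ratio statistic for
#' \eqn{\tau_2 = \tau_3 = 0}.  A single joint test is used because it
#' detects uniform DIF (through \eqn{\tau_2}) and non-uniform DIF
#' (through \eqn{\tau_3}) with one decision per item.
#'
#' @param x N x J binary response matrix.
#' @param group Reference/focal labels.
#' @param item Index of the studied item.
#' @return List with `statistic`, `df` (= 2), `p_value`, the full-model
#'   coefficients `tau`, and both deviances.
#' @export
lr_test <- function(x, group, item) {
  x <- validate_binary_matrix(x, "x")
  J <- ncol(x)
  if (item < 1L || item > J) stop_with("dinadif_invalid", "item index out of range")
  group <- normalize_group(group, nrow(x))
  y <- x[, item]
  if (all(y == y[1L]))
    stop_with("dinadif_untestable", "constant item response")
  M <- rowSums(x)
  G <- as.integer(group == "focal")
  full <- suppressWarnings(glm(y ~ M + G + M:G, family = binomial()))
  red  <- suppressWarnings(glm(y ~ M, family = binomial()))
  if (!full$converged || !red$converged || any(!is.finite(coef(full))))
    stop_with("dinadif_untestable", "logistic fit failed (separation or non-convergence)")
  stat <- red$deviance - full$deviance
  list(statistic = stat, df = 2L,
       p_value = pchisq(stat, df = 2, lower.tail = FALSE),
       tau = setNames(coef(full), c("tau0", "tau1", "tau2", "tau3")),
       deviance_full = full$deviance,
       deviance_reduced = red$deviance)
}
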