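# Internal helpers shared across modules.

# Classed errors so callers (notably the Monte Carlo harness) can
# distinguish a numerically degenerate replication from a coding bug.
stop_with <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "dinadif_error")))
}

clip01 <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

# Parameter vector beta = (g_1, s_1, ..., g_J, s_J, eta_1, ..., eta_{L-1}).
beta_labels <- function(J, L) {
  c(rbind(paste0("g", seq_len(J)), paste0("s", seq_len(J))),
    if (L > 1L) paste0("eta", seq_len(L - 1L)))
}

pack_beta <- function(guess, slip, eta) {
  as.numeric(c(rbind(guess, slip), eta))
}

unpack_beta <- function(beta, J) {
  list(guess = beta[seq(1L, 2L * J, by = 2L)],
       slip  = beta[seq(2L, 2L * J, by = 2L)],
       eta   = beta[-seq_len(2L * J)])
}

# Deterministic stream of child seeds: redrawing replication (i+1) never
# disturbs replication i.  Constants are the Lehmer multiplier and a large
# prime; all arithmetic is exact in doubles (< 2^53) and the result fits
# a 32-bit integer.
child_seed <- function(seed, i) {
  s <- abs(as.double(seed)) %% 2147483647
  out <- (s * 48271 + as.double(i) * 1299709) %% 2147483647
  as.integer(out) + 1L
}

validate_binary_matrix <- function(x, name = "x") {
  x <- as.matrix(x)
  if (!is.numeric(x) && !is.logical(x))
    stop_with("dinadif_invalid", sprintf("`%s` must be numeric", name))
  bad <- which(is.na(x) | !(x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_with("dinadif_invalid",
              sprintf("`%s` must be binary with no missing values; offending entry at row %d, column %d",
                      name, bad[1L, 1L], bad[1L, 2L]))
  storage.mode(x) <- "double"
  x
}

# Map arbitrary two-level group labels onto reference/focal.
normalize_group <- function(group, n, require_both = TRUE) {
  if (length(group) != n)
    stop_with("dinadif_invalid", "`group` must have one label per examinee")
  g <- tolower(as.character(group))
  ref <- g %in% c("r", "ref", "reference", "0")
  foc <- g %in% c("f", "foc", "focal", "1")
  if (any(!ref & !foc))
    stop_with("dinadif_invalid",
              sprintf("unknown group label '%s' (row %d)",
                      group[which(!ref & !foc)[1L]], which(!ref & !foc)[1L]))
  out <- factor(ifelse(ref, "reference", "focal"),
                levels = c("reference", "focal"))
  if (require_both && any(table(out) == 0L))
    stop_with("dinadif_invalid", "both a reference and a focal group are required")
  out
}
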