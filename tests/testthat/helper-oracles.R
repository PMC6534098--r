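# Independent oracles and small-instance generators.  The oracles share
# no code with the implementation: class enumeration goes through
# expand.grid, likelihoods through naive double loops in plain R.

# All 2^K patterns, enumeration order irrelevant for the sums below.
oracle_patterns <- function(K) {
  as.matrix(expand.grid(rep(list(0:1), K)))
}

# Naive marginal log-likelihood: loop over examinees, classes and items.
oracle_loglik <- function(x, guess, slip, eta, q) {
  pat <- oracle_patterns(ncol(q))
  pr_class <- exp(c(eta, 0))
  # match the implementation's class order: eta_l belongs to the l-th
  # pattern in MSB-first binary order, so re-order expand.grid's output
  ord <- order(apply(pat, 1, function(a) sum(a * 2^(rev(seq_along(a)) - 1))))
  pat <- pat[ord, , drop = FALSE]
  pr_class <- pr_class / sum(pr_class)
  total <- 0
  for (n in seq_len(nrow(x))) {
    like_n <- 0
    for (l in seq_len(nrow(pat))) {
      pr <- 1
      for (j in seq_len(nrow(q))) {
        master <- all(pat[l, q[j, ] == 1] == 1)
        pj <- if (master) 1 - slip[j] else guess[j]
        pr <- pr * (if (x[n, j] == 1) pj else 1 - pj)
      }
      like_n <- like_n + pr_class[l] * pr
    }
    total <- total + log(like_n)
  }
  total
}

# Posterior class probabilities by renormalising the naive joint.
oracle_posterior <- function(x, guess, slip, eta, q) {
  pat <- oracle_patterns(ncol(q))
  ord <- order(apply(pat, 1, function(a) sum(a * 2^(rev(seq_along(a)) - 1))))
  pat <- pat[ord, , drop = FALSE]
  pr_class <- exp(c(eta, 0)); pr_class <- pr_class / sum(pr_class)
  t(apply(x, 1, function(xn) {
    joint <- vapply(seq_len(nrow(pat)), function(l) {
      pr <- 1
      for (j in seq_len(nrow(q))) {
        master <- all(pat[l, q[j, ] == 1] == 1)
        pj <- if (master) 1 - slip[j] else guess[j]
        pr <- pr * (if (xn[j] == 1) pj else 1 - pj)
      }
      pr_class[l] * pr
    }, numeric(1))
    joint / sum(joint)
  }))
}

# Central finite-difference gradient of the oracle log-likelihood for
# one examinee, over beta = (g1, s1, ..., gJ, sJ, eta).
oracle_score <- function(xn, guess, slip, eta, q, h = 1e-6) {
  J <- nrow(q)
  beta <- as.numeric(c(rbind(guess, slip), eta))
  f <- function(b) {
    g <- b[seq(1, 2 * J, 2)]; s <- b[seq(2, 2 * J, 2)]; e <- b[-(1:(2 * J))]
    oracle_loglik(matrix(xn, 1), g, s, e, q)
  }
  vapply(seq_along(beta), function(p) {
    bp <- beta; bp[p] <- beta[p] + h
    bm <- beta; bm[p] <- beta[p] - h
    (f(bp) - f(bm)) / (2 * h)
  }, numeric(1))
}

# A small random DINA instance with interior parameters.
random_instance <- function(N, J, K, seed) {
  set.seed(seed)
  repeat {
    q <- matrix(rbinom(J * K, 1, 0.5), J, K)
    if (all(rowSums(q) > 0) && all(colSums(q) > 0)) break
  }
  guess <- runif(J, 0.1, 0.35)
  slip <- runif(J, 0.1, 0.35)
  eta <- rnorm(2^K - 1, 0, 0.5)
  alpha <- matrix(rbinom(N * K, 1, 0.5), N, K)
  x <- sim_dina_responses(alpha, guess, slip, q)
  list(x = x, q = q, guess = guess, slip = slip, eta = eta)
}

# A valid 3-attribute Q-matrix with J items cycling through every
# non-empty loading pattern.
qmat3 <- function(J) {
  base <- attr_patterns(3)[-1, , drop = FALSE]
  q <- base[rep_len(seq_len(7), J), , drop = FALSE]
  rownames(q) <- NULL
  q
}
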