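test_that("analytic scores match finite differences of the log-likelihood", {
  for (i in 1:3) {
    inst <- random_instance(N = 6, J = 3, K = 2, seed = 500 + i)
    S <- dina_scores(inst$x, inst$guess, inst$slip, inst$eta, inst$q)
    expect_equal(ncol(S), 2 * 3 + 3)
    for (n in c(1L, 4L))
      expect_equal(unname(S[n, ]),
                   oracle_score(inst$x[n, ], inst$guess, inst$slip,
                                inst$eta, inst$q),
                   tolerance = 1e-4)
  }

  # parameter count at the study scale: 2*30 + 31 = 91
  inst <- random_instance(N = 2, J = 30, K = 5, seed = 510)
  S <- dina_scores(inst$x, inst$guess, inst$slip, inst$eta, inst$q)
  expect_equal(ncol(S), 91L)
  expect_equal(colnames(S)[c(1, 2, 61)], c("g1", "s1", "eta1"))

  # first-order condition: column sums vanish at the EM solution (a
  # well-identified instance, so no parameter sits on a boundary)
  set.seed(520)
  q <- sim_qmatrix()
  alpha <- sim_attributes(400, 5, 0)
  x <- sim_dina_responses(alpha, rep(0.2, 30), rep(0.2, 30), q)
  fit <- dina(x, q, tol = 1e-9, max_iter = 8000)
  S <- dina_scores(x, fit$guess, fit$slip, fit$eta, fit$q)
  free <- free_params(fit)
  expect_lt(max(abs(colSums(S)[free])), 1e-3)

  inst <- random_instance(N = 2, J = 30, K = 5, seed = 515)
  expect_error(dina_scores(inst$x, rep(0, 30), inst$slip, inst$eta, inst$q),
               class = "dinadif_invalid")
})

test_that("XPD information is the sum of score outer products", {
  expect_equal(unname(info_xpd(matrix(c(1, 2), 1))),
               rbind(c(1, 2), c(2, 4)))
  expect_equal(unname(info_xpd(matrix(0, 4, 3))), matrix(0, 3, 3))

  set.seed(530)
  S <- matrix(rnorm(40), 8, 5)
  I <- info_xpd(S)
  loop <- matrix(0, 5, 5)
  for (n in 1:8) loop <- loop + S[n, ] %o% S[n, ]
  expect_equal(unname(I), loop, tolerance = 1e-12)
  expect_true(all(eigen(I, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("observed information matches a double finite difference of the log-likelihood", {
  inst <- random_instance(N = 40, J = 3, K = 2, seed = 540)
  Io <- info_obs(inst$x, inst$guess, inst$slip, inst$eta, inst$q)
  expect_equal(Io, t(Io))

  # independent oracle: second differences of the total log-likelihood
  beta <- c(rbind(inst$guess, inst$slip), inst$eta)
  P <- length(beta)
  f <- function(b) oracle_loglik(inst$x, b[seq(1, 6, 2)], b[seq(2, 6, 2)],
                                 b[-(1:6)], inst$q)
  h <- 1e-4
  Href <- matrix(0, P, P)
  for (a in seq_len(P)) for (b in seq_len(a)) {
    ea <- eb <- numeric(P); ea[a] <- h; eb[b] <- h
    Href[a, b] <- Href[b, a] <-
      (f(beta + ea + eb) - f(beta + ea - eb) -
       f(beta - ea + eb) + f(beta - ea - eb)) / (4 * h^2)
  }
  expect_equal(unname(Io), -Href, tolerance = 1e-3)

  # information equality: Obs and XPD converge entrywise as N grows
  q <- sim_qmatrix()[c(1:3, 16:18), 1:3]
  gap <- sapply(c(400, 4000), function(N) {
    set.seed(550)
    alpha <- sim_attributes(N, 3, 0)
    x <- sim_dina_responses(alpha, rep(0.2, 6), rep(0.2, 6), q)
    fit <- dina(x, q, tol = 1e-7, max_iter = 3000)
    free <- free_params(fit)
    Ix <- info_xpd(dina_scores(x, fit$guess, fit$slip, fit$eta, q))[free, free]
    Io <- info_obs(x, fit$guess, fit$slip, fit$eta, q)[free, free]
    max(abs(Ix - Io)) / max(abs(Io))
  })
  expect_lt(gap[2], gap[1])
})

test_that("covariances follow the XPD / Obs / sandwich definitions", {
  A <- rbind(c(2, 0.5), c(0.5, 1))
  expect_equal(info_to_vcov("xpd", xpd = A), solve(A))
  expect_equal(info_to_vcov("obs", obs = A), solve(A))
  # coincident information: all three kinds agree
  expect_equal(info_to_vcov("sandwich", xpd = A, obs = A), solve(A),
               tolerance = 1e-12)
  I2 <- diag(2)
  expect_equal(info_to_vcov("sandwich", xpd = I2, obs = I2), I2)
  # hand linear algebra: Obs = diag(2,4), XPD = I  ->  Sw = diag(1/4, 1/16)
  expect_equal(info_to_vcov("sandwich", xpd = diag(2), obs = diag(c(2, 4))),
               diag(c(1 / 4, 1 / 16)))

  expect_error(info_to_vcov("xpd", xpd = matrix(0, 2, 2)),
               class = "dinadif_singular")
  expect_error(info_to_vcov("sandwich", xpd = diag(2)),
               class = "dinadif_invalid")
})

test_that("item-wise blocks invert the per-item score cross-product", {
  set.seed(560)
  q <- qmat3(6)
  alpha <- sim_attributes(400, 3, 0)
  x <- sim_dina_responses(alpha, rep(0.25, 6), rep(0.2, 6), q)
  fit <- dina(x, q)
  blocks <- itemwise_vcov(fit)
  expect_length(blocks, 6L)
  S <- dina_scores(x, fit$guess, fit$slip, fit$eta, q)
  for (j in c(2L, 5L)) {
    B <- crossprod(S[, c(2 * j - 1, 2 * j)])
    # closed-form 2x2 inverse
    det <- B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1]
    inv <- rbind(c(B[2, 2], -B[1, 2]), c(-B[2, 1], B[1, 1])) / det
    expect_equal(unname(blocks[[j]]), inv, tolerance = 1e-8)
    expect_true(all(diag(blocks[[j]]) > 0))
  }

  # the item-wise estimator underestimates the full-information variance
  full <- vcov(fit, type = "xpd")
  v_item <- sapply(seq_len(6), function(j) mean(diag(blocks[[j]])))
  v_full <- sapply(seq_len(6), function(j)
    mean(diag(full[c(2 * j - 1, 2 * j), c(2 * j - 1, 2 * j)])))
  expect_lt(mean(v_item), mean(v_full))
})

test_that("two-group item blocks are assembled in (gF, sF, gR, sR) order", {
  expect_equal(unname(item_cov_block(diag(8), diag(8), 3)), diag(4))

  VF <- matrix(0.1, 8, 8) + diag(8)
  VR <- matrix(0.2, 8, 8) + 2 * diag(8)
  S3 <- item_cov_block(VF, VR, 3)
  expect_equal(rownames(S3), c("gF", "sF", "gR", "sR"))
  expect_equal(S3[1:2, 1:2], VF[5:6, 5:6], ignore_attr = TRUE)
  expect_equal(S3[3:4, 3:4], VR[5:6, 5:6], ignore_attr = TRUE)
  expect_true(all(S3[1:2, 3:4] == 0))        # independent groups
  expect_error(item_cov_block(VF, VR, 9), class = "dinadif_invalid")
})

test_that("standard errors from XPD, Obs and sandwich agree at large N", {
  set.seed(570)
  q <- qmat3(9)
  alpha <- sim_attributes(3000, 3, 0)
  x <- sim_dina_responses(alpha, rep(0.2, 9), rep(0.2, 9), q)
  fit <- dina(x, q, tol = 1e-6, max_iter = 3000)
  se <- sapply(c("xpd", "obs", "sandwich"), function(k)
    sqrt(diag(vcov(fit, type = k))[1:18]))
  expect_lt(max(abs(se[, "obs"] / se[, "xpd"] - 1)), 0.25)
  expect_lt(max(abs(se[, "sandwich"] / se[, "xpd"] - 1)), 0.25)
})
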