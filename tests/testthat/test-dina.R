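test_that("class-conditional response probabilities follow the guess/slip rule", {
  q <- matrix(c(1, 0, 1, 1), 2, 2)          # item 1 needs A1, item 2 needs both
  P <- dina_response_probs(guess = c(0.3, 0.3), slip = c(0.1, 0.1), q)
  expect_equal(dim(P), c(4L, 2L))
  expect_equal(P[4, ], c(0.9, 0.9))          # full mastery: 1 - s
  expect_equal(P[1, ], c(0.3, 0.3))          # no mastery: g
  P2 <- dina_response_probs(rep(0.2, 2), rep(0.2, 2), q)
  expect_true(all(P2 %in% c(0.2, 0.8)))
  expect_error(dina_response_probs(c(0, 0.3), c(0.1, 0.1), q),
               class = "dinadif_invalid")
})

test_that("marginal log-likelihood matches the brute-force class-sum oracle", {
  for (i in 1:4) {
    inst <- random_instance(N = 4, J = 3, K = 2, seed = 200 + i)
    expect_equal(dina_loglik(inst$x, inst$guess, inst$slip, inst$eta, inst$q),
                 oracle_loglik(inst$x, inst$guess, inst$slip, inst$eta, inst$q),
                 tolerance = 1e-10)
  }
  # K = 3 instance as well
  inst <- random_instance(N = 6, J = 4, K = 3, seed = 250)
  expect_equal(dina_loglik(inst$x, inst$guess, inst$slip, inst$eta, inst$q),
               oracle_loglik(inst$x, inst$guess, inst$slip, inst$eta, inst$q),
               tolerance = 1e-10)

  # additivity over examinees
  l1 <- dina_loglik(inst$x[1, , drop = FALSE], inst$guess, inst$slip, inst$eta, inst$q)
  l2 <- dina_loglik(inst$x[2, , drop = FALSE], inst$guess, inst$slip, inst$eta, inst$q)
  l12 <- dina_loglik(inst$x[1:2, , drop = FALSE], inst$guess, inst$slip, inst$eta, inst$q)
  expect_equal(l12, l1 + l2, tolerance = 1e-12)

  # near-noise-free single binary item: P(correct) -> 0.5 under uniform classes
  q1 <- matrix(1, 1, 1)
  ll <- dina_loglik(matrix(1, 1, 1), guess = 1e-9, slip = 1e-9,
                    eta = 0, q = q1)
  expect_equal(ll, log(0.5), tolerance = 1e-6)
})

test_that("posterior class probabilities renormalise the joint", {
  inst <- random_instance(N = 5, J = 4, K = 2, seed = 300)
  W <- dina_posterior(inst$x, inst$guess, inst$slip, inst$eta, inst$q)
  expect_equal(rowSums(W), rep(1, 5), tolerance = 1e-10)
  expect_equal(unname(W),
               unname(oracle_posterior(inst$x, inst$guess, inst$slip,
                                       inst$eta, inst$q)),
               tolerance = 1e-9)

  # noiseless identification: the response pattern of a single-attribute
  # test pins down the class when slip/guess vanish
  q <- diag(2)                              # item k measures attribute k
  W <- dina_posterior(matrix(c(1, 0), 1), rep(1e-9, 2), rep(1e-9, 2),
                      rep(0, 3), q)
  expect_equal(W[1, 3], 1, tolerance = 1e-6)  # pattern (1,0) is class 3

  # flat probabilities give a posterior equal to the prior
  qf <- matrix(c(1, 1), 2, 1)
  Wf <- dina_posterior(matrix(c(1, 0), 1, 2), guess = c(0.5, 0.5),
                       slip = c(0.5, 0.5), eta = 0.7, qf)
  expect_equal(Wf[1, ], class_probs(0.7), tolerance = 1e-12)
})

test_that("EM ascends the likelihood and recovers parameters", {
  # monotone trace on random instances
  for (i in 1:3) {
    inst <- random_instance(N = 80, J = 5, K = 2, seed = 400 + i)
    fit <- dina(inst$x, inst$q, max_iter = 200)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(rowSums(fit$posterior), rep(1, 80), tolerance = 1e-10)
  }

  # tiny instance: EM reaches at least the best point of a parameter grid
  set.seed(440)
  q2 <- matrix(1, 2, 1)
  alpha <- matrix(rbinom(200, 1, 0.5), 200, 1)
  x2 <- sim_dina_responses(alpha, c(0.2, 0.25), c(0.15, 0.2), q2)
  fit2 <- dina(x2, q2, tol = 1e-6)
  gr <- expand.grid(g1 = seq(0.12, 0.28, 0.04), s1 = seq(0.07, 0.23, 0.04),
                    g2 = seq(0.17, 0.33, 0.04), s2 = seq(0.12, 0.28, 0.04),
                    e1 = seq(-0.4, 0.4, 0.2))
  best <- max(vapply(seq_len(nrow(gr)), function(i)
    dina_loglik(x2, c(gr$g1[i], gr$g2[i]), c(gr$s1[i], gr$s2[i]),
                gr$e1[i], q2), numeric(1)))
  expect_gte(fit2$loglik, best - 1e-3)

  # recovery at the study scale, and bias shrinking with N
  q <- sim_qmatrix()
  set.seed(450)
  mae <- sapply(c(500, 2000), function(N) {
    alpha <- sim_attributes(N, 5, rho = 0)
    x <- sim_dina_responses(alpha, rep(0.2, 30), rep(0.2, 30), q)
    f <- dina(x, q)
    mean(abs(c(f$guess - 0.2, f$slip - 0.2)))
  })
  expect_lt(mae[2], 0.03)
  expect_lt(mae[2], mae[1])                  # error shrinks with sample size

  expect_error(dina(matrix(c(0, 2), 1), matrix(1, 2, 1)),
               class = "dinadif_invalid")
})

test_that("two-group fitting is symmetric and deterministic", {
  set.seed(460)
  q <- sim_qmatrix()
  alpha <- sim_attributes(400, 5, 0)
  x <- sim_dina_responses(alpha, rep(0.2, 30), rep(0.2, 30), q)
  grp <- rep(c("R", "F"), each = 200)

  fits <- dina_groups(rbind(x, x), rep(c("R", "F"), each = 400), q)
  expect_equal(fits$reference$guess, fits$focal$guess)
  expect_equal(fits$reference$slip, fits$focal$slip)

  f1 <- dina_groups(x, grp, q)
  f2 <- dina_groups(x, rev(grp), q)          # labels permuted -> outputs swap
  expect_equal(f1$reference$guess, f2$focal$guess)
  expect_equal(f1$focal$loglik, f2$reference$loglik)

  # DIF-free groups: focal/reference estimates agree up to sampling noise
  set.seed(470)
  alpha <- sim_attributes(1000, 5, 0)
  x <- sim_dina_responses(alpha, rep(0.2, 30), rep(0.2, 30), q)
  f <- dina_groups(x, rep(c("R", "F"), each = 500), q)
  expect_lt(mean(abs(f$focal$guess - f$reference$guess)), 0.05)

  w <- capture_warnings(dina_groups(x[1:70, ], rep(c("R", "F"), 35), q))
  expect_match(w, "examinees", all = TRUE)
  expect_length(w, 2L)                       # one warning per small group
})

test_that("dina fit methods behave like a standard modelling object", {
  set.seed(480)
  q <- sim_qmatrix()[1:10, ]
  alpha <- sim_attributes(300, 5, 0.5)
  x <- sim_dina_responses(alpha, rep(0.2, 10), rep(0.25, 10), q)
  fit <- dina(x, q)

  cf <- coef(fit)
  expect_length(cf, 2 * 10 + 31)
  expect_named(cf[1:4], c("g1", "s1", "g2", "s2"))
  expect_equal(unname(cf["g3"]), unname(fit$guess[3]))

  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), fit$npar)

  W <- predict(fit, type = "posterior")
  expect_equal(dim(W), c(300L, 32L))
  cls <- predict(fit, type = "class")
  expect_equal(dim(cls), c(300L, 5L))
  pr <- predict(fit, type = "response")
  expect_true(all(pr > 0 & pr < 1))

  r <- residuals(fit)
  expect_equal(dim(r), dim(x))

  set.seed(1); s1 <- simulate(fit, nsim = 2)
  set.seed(1); s2 <- simulate(fit, nsim = 2)
  expect_identical(s1, s2)
  expect_true(all(s1[[1]] %in% 0:1))

  expect_output(print(fit), "DINA model fit")
  expect_output(print(summary(fit, se_type = "none")), "guess")
})
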