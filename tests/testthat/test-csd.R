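test_that("soft thresholding matches its proximal-operator definition", {
  expect_equal(soft_threshold(matrix(3), 1), matrix(2))
  expect_equal(soft_threshold(matrix(-0.5), 1), matrix(0))
  expect_equal(soft_threshold(matrix(c(-3, 0.2, 0, 5), 2), 0.5),
               matrix(c(-2.5, 0, 0, 4.5), 2))
  set.seed(11)
  A <- matrix(rnorm(16), 4)
  expect_lt(max(abs(soft_threshold(A, 0.3) - oracle_soft_prox(A, 0.3))),
            1e-6)
  expect_error(soft_threshold(A, -0.1), "nonnegative")
})

test_that("Frobenius-ball projection rescales only when outside", {
  A <- matrix(c(3, 0, 4, 0), 2)
  expect_identical(project_frobenius_ball(A, 10), A)
  expect_equal(project_frobenius_ball(A, 1), A / 5)
  set.seed(2)
  B <- matrix(rnorm(12), 3)
  expect_equal(project_frobenius_ball(B, 0), B * 0)
  expect_lte(sqrt(sum(project_frobenius_ball(B, 0.7)^2)), 0.7 + 1e-12)
})

test_that("background update is the row-wise mean minimizer", {
  v <- c(1.5, -2, 7)
  expect_equal(update_background(matrix(v, 3, 5)), v)
  expect_equal(update_background(matrix(c(1, 2, 3, 4), 2)), c(2, 3))
  # derivative-free numeric minimization of gamma/2 ||x.1 - R||_F^2
  set.seed(3)
  R <- matrix(rnorm(35), 5, 7)
  num <- stats::optim(rnorm(5), function(x)
    sum((matrix(x, 5, 7) - R)^2) / 2, method = "Nelder-Mead",
    control = list(maxit = 50000, reltol = 1e-14))$par
  expect_lt(max(abs(update_background(R) - num)), 1e-6)
})

test_that("singular-value thresholding shrinks the spectrum", {
  set.seed(4)
  A <- matrix(rnorm(25), 5)
  expect_lt(max(abs(singular_value_threshold(A, 0) - A)), 1e-10)
  u <- rnorm(6); u <- u / sqrt(sum(u^2))
  v <- rnorm(4); v <- v / sqrt(sum(v^2))
  expect_equal(singular_value_threshold(5 * u %o% v, 2), 3 * u %o% v,
               tolerance = 1e-10)
  # subgradient optimality certificate of the nuclear-norm prox
  X <- singular_value_threshold(A, 1)
  expect_true(svt_certificate_ok(A, X, 1))
})

test_that("common-vector ADMM recovers pure-background input exactly", {
  cvec <- c(5, 1, 9, 2)
  M <- matrix(cvec, 4, 6)
  fit <- decompose_common_vector(M, delta = 0, tol = 1e-10)
  expect_equal(fit$x, cvec, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(fit$Y)), 1e-8)
  expect_lt(max(abs(fit$Z)), 1e-8)
  expect_true(fit$converged)
})

test_that("ADMM recovers the planted toy decomposition at delta = 0", {
  toy <- generate_fig1_toy(seed = 7)
  fit <- decompose_common_vector(toy$M, delta = 0, tol = 1e-9)
  expect_lt(max(abs(csd_background(fit) - toy$background)), 1e-5)
  expect_lt(max(abs(fit$Y - toy$foreground)), 1e-5)
})

test_that("ADMM objective matches the convex optimum (closed form, delta = 0)", {
  for (s in 1:3) {
    inst <- generate_planted(8, 10, 2, 2, matrix(c(5, 0, 0, 0), 2, 2),
                             noise_sd = 0.5, seed = s)
    fit <- decompose_common_vector(inst$M, delta = 0, gamma = 1,
                                   tol = 1e-9, max_iter = 50000)
    opt <- oracle_l1_objective_delta0(inst$M)
    expect_lt(abs(fit$objective - opt) / max(1, opt), 1e-4)
  }
})

test_that("decomposition output is feasible and diagnosed", {
  inst <- generate_planted(10, 12, 2, 2, matrix(c(6, 0, 0, 0), 2, 2),
                           noise_sd = 1, seed = 5)
  fit <- decompose_common_vector(inst$M, delta = 2, tol = 1e-8,
                                 max_iter = 50000)
  m_norm <- max(1, sqrt(sum(inst$M^2)))
  # noise ball and reconstruction constraints
  expect_lte(sqrt(sum(fit$Z^2)), fit$delta + 1e-8)
  resid <- sqrt(sum((csd_background(fit) + fit$Y + fit$Z - inst$M)^2))
  expect_lt(resid / m_norm, 1e-8)
  # the recorded trace ends at the residual the stopping rule saw
  expect_equal(length(fit$primal_residual_trace), fit$iterations)
  expect_equal(utils::tail(fit$primal_residual_trace, 1), resid,
               tolerance = 1e-10)
  # iteration cap -> warning + non-converged flag
  expect_warning(bad <- decompose_common_vector(inst$M, delta = 0,
                                                max_iter = 3),
                 "did not meet")
  expect_false(bad$converged)
})

test_that("a large enough noise budget absorbs the whole foreground", {
  inst <- generate_planted(6, 8, 2, 2, matrix(c(4, 0, 0, 0), 2, 2),
                           noise_sd = 0, seed = 2)
  dev <- sqrt(sum((inst$M - rowMeans(inst$M))^2))
  fit <- decompose_common_vector(inst$M, delta = dev * 1.5, tol = 1e-8,
                                 max_iter = 20000)
  expect_lt(sum(abs(fit$Y)), 1e-6)
})

test_that("optimal foreground mass is nonincreasing in the noise budget", {
  inst <- generate_planted(6, 8, 2, 2, matrix(c(4, 0, 0, 0), 2, 2),
                           noise_sd = 0.5, seed = 9)
  objs <- vapply(c(0, 0.5, 1, 2, 4), function(d)
    decompose_common_vector(inst$M, delta = d, tol = 1e-9,
                            max_iter = 50000)$objective, numeric(1))
  expect_true(all(diff(objs) <= 1e-6))
})

test_that("multi-condition ADMM handles degenerate and planted input", {
  Z0 <- matrix(0, 4, 5)
  fit <- decompose_multi_condition(list(Z0, Z0), delta = 0, tol = 1e-8)
  expect_lt(max(abs(fit$X)), 1e-8)
  expect_lt(max(abs(fit$Y_list[[1]])), 1e-8)
  expect_error(
    decompose_multi_condition(list(Z0, matrix(0, 3, 5))),
    "identical dimensions")
})

test_that("K = 1 low-rank objective matches a Douglas-Rachford solve", {
  inst <- generate_planted(8, 8, 2, 2, matrix(c(5, 0, 0, 0), 2, 2),
                           noise_sd = 0.5, seed = 3)
  M <- unname(inst$M)
  rho <- 0.3
  fit <- decompose_multi_condition(list(M), rho_list = rho, delta = 0,
                                   tol = 1e-10, max_iter = 50000)
  obj <- sum(svd(fit$X, nu = 0, nv = 0)$d) + rho * sum(abs(fit$Y_list[[1]]))
  opt <- oracle_dr_nuclear_l1(M, rho)
  expect_lt(abs(obj - opt) / opt, 1e-4)
})

test_that("rank-one-constrained multi-condition solve equals the common-vector solve", {
  inst <- generate_planted(8, 8, 2, 2, matrix(c(5, 0, 0, 0), 2, 2),
                           noise_sd = 0.5, seed = 4)
  M <- unname(inst$M)
  f1 <- decompose_common_vector(M, delta = 0.3, tol = 1e-10,
                                max_iter = 50000)
  f3 <- decompose_multi_condition(list(M), rho_list = 1, delta = 0.3,
                                  tol = 1e-10, max_iter = 50000,
                                  common_vector = TRUE)
  expect_lt(max(abs(f1$Y - f3$Y_list[[1]])), 1e-5)
  expect_lt(max(abs(f1$x - f3$x)), 1e-5)
})
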