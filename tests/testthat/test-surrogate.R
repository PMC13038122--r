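test_that("basis enumeration matches exhaustive oracles and edge cases", {
  ## 1 parameter, cap 3: constant + orders 1..3
  s1 <- basis_spec(max_univariate_order = 3, gradient_param_order = 3,
                   max_interaction_order = 1, max_interaction_sum = 3,
                   gradient_param_index = 1)
  expect_equal(nrow(enumerate_basis(s1, 1)), 4)

  ## 2 parameters, caps 2, interaction order 2, interaction sum 2: 6
  s2 <- basis_spec(max_univariate_order = 2, gradient_param_order = 2,
                   max_interaction_order = 2, max_interaction_sum = 2,
                   gradient_param_index = 1)
  expect_equal(nrow(enumerate_basis(s2, 2)), 6)

  ## brute-force filter over the full tensor grid for 3 params
  s3 <- basis_spec(max_univariate_order = 6, gradient_param_order = 4,
                   max_interaction_order = 2, max_interaction_sum = 5,
                   gradient_param_index = 2)
  mi <- enumerate_basis(s3, 3)
  grid <- as.matrix(expand.grid(0:6, 0:6, 0:6))
  keep <- apply(grid, 1, function(a) {
    nz <- sum(a > 0)
    if (a[2] > 4) return(FALSE)
    if (nz > 2) return(FALSE)
    if (nz == 1 && max(a) > 6) return(FALSE)
    if (nz >= 2 && sum(a) > 5) return(FALSE)
    TRUE
  })
  expect_equal(nrow(mi), sum(keep))
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(key(mi), key(grid[keep, , drop = FALSE]))

  ## uniqueness and the constant term
  expect_equal(anyDuplicated(apply(mi, 1, paste, collapse = ",")), 0)
  expect_true(any(rowSums(mi) == 0))
})

test_that("parameter sampling is reproducible, in-bounds, and uniform in
           the mean", {
  b <- param_bounds()
  x1 <- sample_params(b, 4000, seed = 5)
  x2 <- sample_params(b, 4000, seed = 5)
  expect_identical(x1, x2)
  expect_true(all(sweep(x1, 2, b[, 1], `>=`)))
  expect_true(all(sweep(x1, 2, b[, 2], `<=`)))
  mid <- (b[, 1] + b[, 2]) / 2
  se <- (b[, 2] - b[, 1]) / sqrt(12) / sqrt(4000)
  expect_true(all(abs(colMeans(x1) - mid) < 3 * se))
})

test_that("gPC fit recovers exactly representable responses to machine
           precision", {
  b <- param_bounds(rbind(a = c(-1, 2), b = c(0, 5)))
  spec <- basis_spec(max_univariate_order = 4, gradient_param_order = 4,
                     max_interaction_order = 2, max_interaction_sum = 6,
                     gradient_param_index = 1)
  x <- sample_params(b, 300, seed = 2)
  u <- sweep(sweep(x, 2, (b[, 1] + b[, 2]) / 2), 2,
             (b[, 2] - b[, 1]) / 2, `/`)
  ## polynomial inside the span
  y <- 2 + 3 * u[, 1] - u[, 2]^3 + 0.5 * u[, 1]^2 * u[, 2]
  fit <- fit_gpc(x, cbind(y), spec, b)
  xt <- sample_params(b, 200, seed = 9)
  ut <- sweep(sweep(xt, 2, (b[, 1] + b[, 2]) / 2), 2,
              (b[, 2] - b[, 1]) / 2, `/`)
  yt <- 2 + 3 * ut[, 1] - ut[, 2]^3 + 0.5 * ut[, 1]^2 * ut[, 2]
  expect_lt(nrmsd(cbind(yt), predict(fit, xt)), 1e-8)
  expect_equal(drop(predict(fit, x)), y, tolerance = 1e-8)

  ## constant response: only the constant coefficient survives
  fitc <- fit_gpc(x, cbind(rep(4.2, nrow(x))), spec, b)
  const_row <- which(rowSums(fitc$multi_indices) == 0)
  expect_equal(fitc$coefficients[const_row, 1], 4.2, tolerance = 1e-10)
  expect_lt(max(abs(fitc$coefficients[-const_row, 1])), 1e-10)

  ## first-degree Legendre of parameter 1: coefficient pattern recovered;
  ## the orthonormal family carries sqrt(3) on degree 1
  y1 <- sqrt(3) * u[, 1]
  fit1 <- fit_gpc(x, cbind(y1), spec, b)
  row1 <- which(fit1$multi_indices[, 1] == 1 &
                rowSums(fit1$multi_indices) == 1)
  expect_equal(unname(fit1$coefficients[row1, 1]), 1, tolerance = 1e-8)
  expect_lt(max(abs(fit1$coefficients[-row1, 1])), 1e-8)
})

test_that("the orthonormal Legendre family is orthonormal under the
           uniform measure", {
  ## trapezoid quadrature oracle on a dense grid, uniform density 1/2
  x <- seq(-1, 1, length.out = 20001)
  dx <- x[2] - x[1]
  w <- c(0.5, rep(1, length(x) - 2), 0.5) * dx / 2
  P <- tmskernels:::.legendre_norm(x, 6)
  G <- crossprod(P, P * w)
  expect_equal(unname(as.matrix(G)), diag(7), tolerance = 1e-5)
})

test_that("prediction is linear in coefficients and consistent with
           scalar evaluation", {
  b <- param_bounds(rbind(a = c(0, 1), b = c(0, 1)))
  spec <- basis_spec(max_univariate_order = 3, gradient_param_order = 3,
                     max_interaction_order = 2, max_interaction_sum = 4,
                     gradient_param_index = 1)
  x <- sample_params(b, 100, seed = 3)
  y <- cbind(sin(x[, 1]) + x[, 2], cos(x[, 2]))
  fit <- fit_gpc(x, y, spec, b)
  xt <- sample_params(b, 7, seed = 4)
  pv <- predict(fit, xt)
  ps <- t(sapply(seq_len(7), function(i) predict(fit, xt[i, , drop = FALSE])))
  expect_equal(pv, ps, tolerance = 1e-12)
  fit2 <- fit
  fit2$coefficients <- 2 * fit$coefficients
  expect_equal(predict(fit2, xt), 2 * pv, tolerance = 1e-12)
})

test_that("NRMSD matches hand evaluation and affine invariance", {
  expect_equal(as.numeric(nrmsd(cbind(c(1, 2)), cbind(c(1, 2)))), 0)
  ## single time point, ref {0, 2}, approx {1, 1}: RMS 1, range 2 -> 50%
  expect_equal(as.numeric(nrmsd(cbind(c(0, 2)), cbind(c(1, 1)))), 50)
  set.seed(1)
  r <- matrix(rnorm(40), 10, 4)
  a <- r + matrix(rnorm(40, sd = 0.1), 10, 4)
  e1 <- as.numeric(nrmsd(r, a))
  e2 <- as.numeric(nrmsd(3 * r - 2, 3 * a - 2))
  expect_equal(e2, e1, tolerance = 1e-12)
  ## zero-range time point excluded with diagnostic
  r2 <- cbind(r[, 1], 5)
  a2 <- cbind(a[, 1], 5)
  out <- nrmsd(r2, a2)
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("Sobol indices reproduce the closed-form variance decomposition
           of an additive model", {
  b <- param_bounds(rbind(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1)))
  spec <- basis_spec(max_univariate_order = 3, gradient_param_order = 3,
                     max_interaction_order = 2, max_interaction_sum = 4,
                     gradient_param_index = 1)
  x <- sample_params(b, 400, seed = 6)
  aa <- 2; bb <- 0.5
  y <- cbind(aa * x[, 1] + bb * x[, 2])
  fit <- fit_gpc(x, y, spec, b)
  s <- sobol_indices(fit)
  ## Var = a^2/3 + b^2/3; S1 = a^2 / (a^2 + b^2)
  i1 <- which(s$support == "1"); i2 <- which(s$support == "2")
  expect_equal(s$sobol[i1, 1], aa^2 / (aa^2 + bb^2), tolerance = 1e-8)
  expect_equal(s$sobol[i2, 1], bb^2 / (aa^2 + bb^2), tolerance = 1e-8)
  others <- setdiff(seq_along(s$support), c(i1, i2))
  expect_lt(max(s$sobol[others, 1]), 1e-8)
  expect_equal(sum(s$sobol[, 1]), 1, tolerance = 1e-9)

  ## single-parameter model: all variance on that support
  y1 <- cbind(x[, 3]^2)
  s1 <- sobol_indices(fit_gpc(x, y1, spec, b))
  i3 <- which(s1$support == "3")
  expect_equal(s1$sobol[i3, 1], 1, tolerance = 1e-8)
})

test_that("gPC Sobol indices agree with Monte-Carlo (Saltelli) estimates
           on a 3-parameter toy model", {
  b <- param_bounds(rbind(a = c(0, 1), b = c(0, 1), c = c(0, 1)))
  f <- function(x) sin(pi * x[, 1]) + 0.5 * x[, 2]^2 +
    0.25 * x[, 1] * x[, 3]
  spec <- basis_spec(max_univariate_order = 8, gradient_param_order = 8,
                     max_interaction_order = 3, max_interaction_sum = 8,
                     gradient_param_index = 1)
  x <- sample_params(b, 1500, seed = 11)
  fit <- fit_gpc(x, cbind(f(x)), spec, b)
  s <- sobol_indices(fit)
  ## Saltelli-style first-order MC estimator (independent oracle)
  set.seed(99)
  n <- 2e5
  A <- matrix(runif(3 * n), n, 3)
  B <- matrix(runif(3 * n), n, 3)
  yA <- f(A); yB <- f(B)
  V <- var(c(yA, yB))
  first_mc <- vapply(1:3, function(j) {
    AB <- A; AB[, j] <- B[, j]
    mean(yB * (f(AB) - yA)) / V
  }, numeric(1))
  total <- sum(s$variance)
  first_gpc <- vapply(c("1", "2", "3"), function(k) {
    i <- which(s$support == k)
    if (length(i)) s$sobol[i, 1] else 0
  }, numeric(1))
  expect_lt(max(abs(first_gpc - first_mc)), 0.02)
})

test_that("derivative sensitivities are exact for linear models, vanish
           under even symmetry, and are seed-stable", {
  b <- param_bounds(rbind(a = c(0, 2), b = c(-3, 1)))
  spec <- basis_spec(max_univariate_order = 4, gradient_param_order = 4,
                     max_interaction_order = 2, max_interaction_sum = 5,
                     gradient_param_index = 1)
  x <- sample_params(b, 200, seed = 8)
  y <- cbind(3 * x[, 1] - 0.5 * x[, 2])
  fit <- fit_gpc(x, y, spec, b)
  d <- derivative_sensitivity(fit, n_mc = 5000, seed = 2)
  expect_equal(unname(d[, 1]), c(3, -0.5), tolerance = 1e-6)

  ## even function about the midpoint of parameter 1: E[d/dx1] -> 0
  mid <- 1
  y2 <- cbind((x[, 1] - mid)^2)
  fit2 <- fit_gpc(x, y2, spec, b)
  d2 <- derivative_sensitivity(fit2, n_mc = 20000, seed = 3)
  ## MC SE of d/dx1 of (x-mid)^2 with x ~ U(0,2): sd = 2/sqrt(12)*2
  se <- 2 * (2 - 0) / sqrt(12) / sqrt(20000)
  expect_lt(abs(d2[1, 1]), 3 * se)

  d3 <- derivative_sensitivity(fit, n_mc = 5000, seed = 2)
  expect_identical(d, d3)
})

test_that("the surrogate time grid is half-open with the documented
           resolution", {
  tg <- surrogate_time_grid()
  expect_length(tg, 500)
  expect_equal(tg[1], 0)
  expect_equal(tg[2] - tg[1], 0.2)
  expect_lt(max(tg), 100)
  tg2 <- surrogate_time_grid(50, 0.5)
  expect_length(tg2, 100)
})

test_that("NRMSD of a smooth target decreases with training size", {
  b <- param_bounds(rbind(a = c(0, 1), b = c(0, 1)))
  f <- function(x) exp(-x[, 1]) * sin(2 * x[, 2])
  spec <- basis_spec(max_univariate_order = 6, gradient_param_order = 6,
                     max_interaction_order = 2, max_interaction_sum = 8,
                     gradient_param_index = 1)
  xt <- sample_params(b, 500, seed = 20)
  yt <- cbind(f(xt))
  errs <- vapply(c(60, 200, 800), function(n) {
    x <- sample_params(b, n, seed = 21)
    fit <- fit_gpc(x, cbind(f(x)), spec, b)
    as.numeric(nrmsd(yt, predict(fit, xt)))
  }, numeric(1))
  expect_true(errs[3] <= errs[1])
})
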