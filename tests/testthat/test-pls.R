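test_that("NIPALS matches the eigen-decomposition PLS1 oracle", {
  set.seed(42)
  for (i in 1:100) {
    X <- matrix(rnorm(48), 8, 6, dimnames = list(NULL, paste0("P", 1:6)))
    y <- rnorm(8)
    A <- sample(1:3, 1)
    m <- pls_fit(X, y, A)
    o <- oracle_pls1(X, y, A)
    expect_equal(unname(m$coef_scaled), o$coef_scaled, tolerance = 1e-8)
    expect_equal(abs(unname(m$weights)), abs(unname(o$weights)),
                 tolerance = 1e-8)
    expect_equal(sum(vip_scores(m)^2), 6, tolerance = 1e-8)
  }
})

test_that("NIPALS agrees with an established PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  X <- matrix(rnorm(80), 10, 8, dimnames = list(NULL, paste0("P", 1:8)))
  y <- rnorm(10)
  m <- pls_fit(X, y, 2)
  mo <- mixOmics::pls(X, data.frame(y = y), ncomp = 2, mode = "regression",
                      scale = TRUE)
  expect_equal(abs(unname(m$scores)), abs(unname(mo$variates$X)),
               tolerance = 1e-10)
  expect_equal(unname(vip_scores(m)), unname(mixOmics::vip(mo)[, 2]),
               tolerance = 1e-10)
})

test_that("model structure invariants hold", {
  set.seed(10)
  X <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("P", 1:6)))
  y <- drop(X %*% c(2, -1, 0, 0, 0.5, 0)) + rnorm(10, sd = 0.2)
  m <- pls_fit(X, y, 4)
  # successive score vectors are mutually orthogonal
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-9)
  # explained variances are in [0, 1] and non-decreasing in A
  expect_true(all(m$r2x >= 0 & m$r2x <= 1))
  expect_true(all(m$r2y >= 0 & m$r2y <= 1))
  expect_true(all(diff(m$r2x) >= -1e-12))
  expect_true(all(diff(m$r2y) >= -1e-12))
  # coefficients reproduce the fitted values
  expect_equal(m$fitted, drop(X %*% m$coefficients) + m$intercept)
})

test_that("a response proportional to one column is explained by one component", {
  set.seed(2)
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("P", 1:5)))
  # make the remaining columns orthogonal to the driving one, so the first
  # weight vector points exactly along it
  X[, 2] <- X[, 2] - mean(X[, 2])
  for (j in c(1, 3, 4, 5)) X[, j] <- resid(lm(X[, j] ~ X[, 2]))
  y <- 3 * X[, 2]
  m <- pls_fit(X, y, 1)
  expect_equal(m$r2y[1], 1, tolerance = 1e-10)
  expect_equal(predict(m, X), y, tolerance = 1e-8)
})

test_that("centering makes coefficients invariant to a response shift", {
  set.seed(4)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("P", 1:5)))
  y <- rnorm(8)
  m1 <- pls_fit(X, y, 2)
  m2 <- pls_fit(X, y + 100, 2)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
})

test_that("coefficients are stable under predictor reordering", {
  set.seed(12)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("P", 1:5)))
  y <- rnorm(8)
  perm <- c(3, 1, 5, 2, 4)
  m1 <- pls_fit(X, y, 2)
  m2 <- pls_fit(X[, perm], y, 2)
  expect_equal(m1$coefficients[colnames(X)[perm]], m2$coefficients,
               tolerance = 1e-10)
})

test_that("degenerate inputs are handled", {
  X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("P", 1:5)))
  y <- rnorm(8)
  expect_error(pls_fit(X, y, 8), "ncomp too large")
  expect_error(pls_fit(X, rep(1, 8), 1), "zero variance")
  X[, 3] <- 7
  expect_warning(m <- pls_fit(X, y, 2), "zero-variance")
  expect_equal(length(m$peaks), 4)
  # VIP of a single-predictor model is exactly 1
  m1 <- suppressWarnings(pls_fit(X[, c(1, 3)], y, 1))
  expect_equal(unname(vip_scores(m1)), 1)
})

test_that("leave-one-out Q2 is high for a noiseless linear response", {
  set.seed(20)
  # with A able to reach the predictor rank, PLS spans the full X space and
  # the noiseless linear response is predicted exactly in every fold
  X <- matrix(rlnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("P", 1:5)))
  y <- drop(X[, 1:3] %*% c(1, 2, 1))
  cv <- cv_q2(X, y, ncomp_max = 5)
  expect_gte(max(cv$q2), 0.99)
  expect_equal(cv$q2[cv$ncomp], max(cv$q2), tolerance = 0.0101)
})

test_that("Q2 of a pure-noise response is non-positive on average", {
  set.seed(30)
  q2s <- replicate(25, {
    X <- matrix(rnorm(100), 10, 10, dimnames = list(NULL, paste0("P", 1:10)))
    y <- rnorm(10)
    cv_q2(X, y, ncomp_max = 2)$q2[1]
  })
  expect_lt(mean(q2s), 0)
})

test_that("selection requires VIP above 1 and a positive coefficient", {
  d <- tiny_dataset(seed = 25, n_peaks = 8, active = c(1, 5), noise = 0)
  scr <- plsr_screen(d$matrix, d$effects)
  sel <- scr$endpoints$frap$selected
  planted <- d$truth$active_sets$frap
  expect_true(all(planted %in% sel))
  sc <- scr$endpoints$frap$scores
  expect_true(all(sc$vip[match(sel, sc$peak)] > 1))
  expect_true(all(sc$coefficient[match(sel, sc$peak)] > 0))
  # sign-agnostic mode can only grow the set
  m <- pls_fit(d$matrix$areas, d$effects$activity$frap,
               scr$endpoints$frap$model$ncomp)
  sel2 <- pls_select(m, require_positive = FALSE)
  expect_true(all(sel %in% sel2))
  # an impossible threshold empties the selection
  expect_length(pls_select(m, vip_threshold = Inf), 0)
})
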