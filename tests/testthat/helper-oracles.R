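# Independent oracle implementations used to cross-check the package.
# Deliberately written along different computational routes than R/.

# PLS1 via per-component eigen-decomposition: the weight of each component
# is the dominant eigenvector of E' f f' E (computed by eigen(), not by
# normalising E'f), deflation and regression assembled independently.
oracle_pls1 <- function(X, y, ncomp) {
  E <- scale(X); f <- drop(scale(y))
  ys <- attr(scale(y), "scaled:scale")
  W <- P <- NULL; q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    cov <- drop(crossprod(E, f))
    M <- tcrossprod(cov)
    ev <- eigen(M, symmetric = TRUE)
    w <- ev$vectors[, 1]
    if (sum(w * cov) < 0) w <- -w
    tt <- drop(E %*% w)
    p <- drop(crossprod(E, tt)) / sum(tt^2)
    q[a] <- sum(f * tt) / sum(tt^2)
    E <- E - tcrossprod(tt, p)
    f <- f - tt * q[a]
    W <- cbind(W, w); P <- cbind(P, p)
  }
  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  list(coef_scaled = b_scaled, weights = W)
}

# Wold VIP evaluated directly from a model's stored weights and
# per-component explained y sums of squares.
oracle_vip <- function(weights, ssy) {
  p <- nrow(weights)
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(ncol(weights)))
      acc <- acc + ssy[a] * (weights[j, a] / sqrt(sum(weights[, a]^2)))^2
    out[j] <- sqrt(p * acc / sum(ssy))
  }
  out
}

# Deng grey coefficients by literal double-loop evaluation of the defining
# formula (global min/max over all comparison sequences and positions).
oracle_grey <- function(x0, X, rho = 0.5) {
  X <- as.matrix(X)
  N <- length(x0); p <- ncol(X)
  dmin <- Inf; dmax <- -Inf
  for (s in seq_len(p)) for (t in seq_len(N)) {
    d <- abs(x0[t] - X[t, s])
    if (d < dmin) dmin <- d
    if (d > dmax) dmax <- d
  }
  xi <- matrix(NA_real_, N, p)
  for (i in seq_len(p)) for (k in seq_len(N))
    xi[k, i] <- (dmin + rho * dmax) / (abs(x0[k] - X[k, i]) + rho * dmax)
  list(xi = xi, r = colMeans(xi))
}

# Brute-force 4PL least squares: grid over (log IC50, hill), with floor and
# ceiling profiled out by linear least squares at each grid point.
oracle_4pl_ss <- function(x, y, n_grid = 120) {
  lic <- seq(log(min(x)) - 1, log(max(x)) + 1, length.out = n_grid)
  hills <- c(-seq(0.2, 4, length.out = 40), seq(0.2, 4, length.out = 40))
  best <- list(ss = Inf)
  for (l in lic) for (h in hills) {
    s <- 1 / (1 + exp(h * (l - log(x))))
    fit <- lm(y ~ s)
    ss <- sum(resid(fit)^2)
    if (ss < best$ss)
      best <- list(ss = ss, ic50 = exp(l), hill = h,
                   bottom = coef(fit)[1], top = sum(coef(fit)))
  }
  best
}

# Nearest-RT assignment between two peak tables (unique nearest neighbour
# both ways), for small instances.
oracle_rt_match <- function(rt1, rt2, tol) {
  pairs <- lapply(seq_along(rt1), function(i) {
    j <- which.min(abs(rt2 - rt1[i]))
    if (abs(rt2[j] - rt1[i]) <= 2 * tol) c(i, j) else NULL
  })
  pairs <- do.call(rbind, pairs)
  stopifnot(!anyDuplicated(pairs[, 2]))
  pairs
}

# small synthetic dataset helper used across tests
tiny_dataset <- function(seed = 1, n_peaks = 8, active = 1:3, noise = 0,
                         endpoint = "frap") {
  as_list <- list(active)
  names(as_list) <- endpoint
  spec <- synthetic_spec(n_batches = 10, n_peaks = n_peaks,
                         active_sets = as_list, noise_sd = noise,
                         seed = seed)
  gen_spectrum_effect(spec)
}
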