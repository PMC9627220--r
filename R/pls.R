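#' NIPALS PLS1 regression
#'
#' Partial least squares regression of a single response on the peak-area
#' matrix, by the NIPALS algorithm on autoscaled (centred, unit-variance)
#' data. Per component `a`: the X-weight `w_a` is the normalised covariance
#' direction `E'f / ||E'f||`, scores `t_a = E w_a`, X-loadings
#' `p_a = E't_a / t_a't_a`, y-loading `q_a = f't_a / t_a't_a`, followed by
#' deflation of `E` and `f`. Regression coefficients on the autoscaled
#' predictors are `W (P'W)^{-1} q`, back-transformed to the original scale.
#'
#' Zero-variance columns are dropped with a warning (they cannot be
#' autoscaled and carry no information).
#'
#' @param X Numeric matrix, batches x peaks (n >= 2).
#' @param y Numeric response (activity), length n.
#' @param ncomp Number of components A, `<= min(n - 1, p)`.
#' @return Object of class `pls_model`: `scores` (T), `weights` (W),
#'   `loadings` (P), `y_loadings` (q), `coefficients` (original scale),
#'   `intercept`, `coef_scaled`, `r2x`, `r2y` (cumulative per component),
#'   `ssy` (per-component explained y sum of squares), `fitted`,
#'   `x_center`, `x_scale`, `y_center`, `y_scale`, `peaks`, `ncomp`.
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  keep <- apply(X, 2, function(v) sd(v) > 0)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  if (ncomp > min(n - 1, p))
    stop("ncomp too large: must be <= min(n - 1, p) = ", min(n - 1, p))
  if (sd(y) == 0) stop("response has zero variance")

  xc <- colMeans(X); xs <- apply(X, 2, sd)
  yc <- mean(y); ys <- sd(y)
  E <- sweep(sweep(X, 2, xc), 2, xs, "/")
  f <- (y - yc) / ys
  ssx_tot <- sum(E^2); ssy_tot <- sum(f^2)

  W <- P <- Tm <- NULL
  q <- t2 <- ssy <- r2x <- r2y <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop("no remaining covariance at component ", a)
    w <- w / nw
    tt <- drop(E %*% w)
    t2[a] <- sum(tt^2)
    pp <- drop(crossprod(E, tt)) / t2[a]
    q[a] <- sum(f * tt) / t2[a]
    E <- E - tcrossprod(tt, pp)
    f <- f - tt * q[a]
    W <- cbind(W, w); P <- cbind(P, pp); Tm <- cbind(Tm, tt)
    ssy[a] <- q[a]^2 * t2[a]
    r2x[a] <- 1 - sum(E^2) / ssx_tot
    r2y[a] <- 1 - sum(f^2) / ssy_tot
  }
  colnames(W) <- colnames(P) <- colnames(Tm) <- paste0("comp", seq_len(ncomp))
  rownames(W) <- rownames(P) <- colnames(X)

  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  b_orig <- b_scaled * ys / xs
  intercept <- yc - sum(b_orig * xc)
  fitted <- drop(X %*% b_orig) + intercept

  structure(list(
    scores = Tm, weights = W, loadings = P, y_loadings = q,
    coefficients = setNames(b_orig, colnames(X)), intercept = intercept,
    coef_scaled = setNames(b_scaled, colnames(X)),
    r2x = r2x, r2y = r2y, ssy = ssy, t2 = t2, fitted = fitted,
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    peaks = colnames(X), ncomp = ncomp
  ), class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$peaks, drop = FALSE]
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS1 model:", length(x$peaks), "predictors,", x$ncomp, "components\n")
  cat("  cumulative R2X:", paste(sprintf("%.3f", x$r2x), collapse = " "), "\n")
  cat("  cumulative R2Y:", paste(sprintf("%.3f", x$r2y), collapse = " "), "\n")
  invisible(x)
}

#' Variable influence on projection (VIP)
#'
#' Wold's VIP for predictor `j` over the `A` components:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja} / \|w_a\|)^2 / \sum_a SSY_a}}
#' where `SSY_a` is the y sum of squares explained by component `a`. The
#' scores satisfy `sum(VIP^2) = p`, so values above 1 flag predictors of
#' above-average influence.
#'
#' @param model A `pls_model`.
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (sum(model$ssy) <= 0) stop("model explains no y variance")
  W2 <- sweep(model$weights^2, 2, colSums(model$weights^2), "/")
  sqrt(length(model$peaks) * drop(W2 %*% model$ssy) / sum(model$ssy))
}

#' Cross-validated Q2 and component-number selection
#'
#' `Q2(A) = 1 - PRESS(A) / TSS` with per-fold refitting (leave-one-out by
#' default: with ~10 batches, k-fold splits are unstable). The number of
#' components is chosen as the smallest `A` whose Q2 is within `plateau` of
#' the maximum over `A <= ncomp_max` -- additional components must earn
#' their keep.
#'
#' @param X Predictor matrix (batches x peaks).
#' @param y Response.
#' @param ncomp_max Largest A tried (default 5, capped by the data).
#' @param folds Number of folds (default n, i.e. leave-one-out).
#' @param plateau Tolerance of the plateau rule (default 0.01).
#' @return List: `q2` (vector over A), `ncomp` (chosen A), `press`, `tss`.
#' @export
cv_q2 <- function(X, y, ncomp_max = 5, folds = nrow(X), plateau = 0.01) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2) stop("folds must be >= 2")
  if (folds > n) folds <- n
  ncomp_max <- min(ncomp_max, n - 2, ncol(X))
  assign_fold <- rep_len(seq_len(folds), n)
  press <- numeric(ncomp_max)
  for (k in seq_len(folds)) {
    hold <- which(assign_fold == k)
    if (sd(y[-hold]) == 0) stop("fold ", k, ": training response has zero variance")
    for (A in seq_len(ncomp_max)) {
      m <- pls_fit(X[-hold, , drop = FALSE], y[-hold], A)
      pred <- predict(m, X[hold, , drop = FALSE])
      press[A] <- press[A] + sum((y[hold] - pred)^2)
    }
  }
  tss <- sum((y - mean(y))^2)
  q2 <- 1 - press / tss
  ncomp <- min(which(q2 >= max(q2) - plateau))
  list(q2 = q2, ncomp = ncomp, press = press, tss = tss)
}

#' Select peaks from a PLS model by VIP and coefficient sign
#'
#' The screening rule: VIP strictly above the threshold *and* a strictly
#' positive regression coefficient (a peak must be positively correlated
#' with activity to be a candidate active constituent). Set
#' `require_positive = FALSE` for a sign-agnostic sensitivity analysis.
#'
#' @param model A `pls_model`.
#' @param vip VIP scores from [vip_scores()] (recomputed if missing).
#' @param vip_threshold Threshold (default 1).
#' @param require_positive Require `coefficient > 0` (default TRUE).
#' @return Character vector of selected peak ids.
#' @export
pls_select <- function(model, vip = NULL, vip_threshold = 1,
                       require_positive = TRUE) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(vip)) vip <- vip_scores(model)
  sel <- vip > vip_threshold
  if (require_positive) sel <- sel & model$coef_scaled > 0
  model$peaks[sel]
}

#' PLS/VIP screen of peaks against each effect endpoint
#'
#' Per endpoint: choose the component count by leave-one-out Q2 (plateau
#' rule), fit the NIPALS model on all batches, and select peaks with
#' VIP > 1 and positive coefficient.
#'
#' @inheritParams gra_select
#' @param vip_threshold VIP selection threshold (default 1).
#' @param ncomp_max Largest component count tried (default 5).
#' @param require_positive Require positive coefficients (default TRUE).
#' @return Object of class `plsr_result`: per endpoint `scores` (peak, vip,
#'   coefficient), `selected`, `model` stats (`r2x`, `r2y`, `q2`, `ncomp`).
#' @export
plsr_screen <- function(matrix, effects, vip_threshold = 1, ncomp_max = 5,
                        require_positive = TRUE) {
  A <- if (inherits(matrix, "common_peak_matrix")) matrix$areas else matrix
  stopifnot(inherits(effects, "effect_table"))
  out <- list()
  for (e in effects$meta$endpoint) {
    y <- effects$activity[[e]]
    cv <- cv_q2(A, y, ncomp_max = ncomp_max)
    m <- pls_fit(A, y, cv$ncomp)
    vip <- vip_scores(m)
    sel <- pls_select(m, vip, vip_threshold, require_positive)
    out[[e]] <- list(
      scores = data.frame(peak = m$peaks, vip = unname(vip),
                          coefficient = unname(m$coef_scaled),
                          stringsAsFactors = FALSE),
      selected = sel,
      model = list(ncomp = cv$ncomp, q2 = cv$q2[cv$ncomp],
                   q2_by_ncomp = cv$q2,
                   r2x = m$r2x[cv$ncomp], r2y = m$r2y[cv$ncomp]))
  }
  structure(list(endpoints = out, vip_threshold = vip_threshold,
                 require_positive = require_positive),
            class = "plsr_result")
}

#' @export
print.plsr_result <- function(x, ...) {
  cat("PLS/VIP screen (VIP >", x$vip_threshold,
      if (x$require_positive) "and coefficient > 0" else "", ")\n")
  for (e in names(x$endpoints)) {
    m <- x$endpoints[[e]]$model
    cat(sprintf("  %-10s A=%d R2X=%.3f R2Y=%.3f Q2=%.3f  %d peaks\n", e,
                m$ncomp, m$r2x, m$r2y, m$q2,
                length(x$endpoints[[e]]$selected)))
  }
  invisible(x)
}
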